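# Segmentation by Otsu's method applied iteratively (cascaded). A single
# Otsu threshold separates two intensity populations; fluorescence scans of
# bone sections often carry three (background outside the bone, marrow-space
# background, signal). Re-running Otsu on the surviving foreground pixels
# isolates the brightest population without being dominated by the global
# histogram.

#' Otsu threshold of an intensity sample
#'
#' Builds a 256-bin histogram over the observed min-max range and returns
#' the bin boundary maximizing the between-class variance (equivalently,
#' minimizing the intraclass variance). Ties are broken toward the lower
#' threshold. Foreground is `value > threshold`.
#'
#' @param values numeric intensity sample with at least 2 distinct values.
#' @param nbins histogram resolution (default 256).
#' @return the threshold intensity.
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2L || rng[1] == rng[2])
    stop("degenerate histogram: need at least 2 distinct values")
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(values, breaks, all.inside = TRUE), 1L), nbins)
  counts <- as.numeric(tabulate(bin, nbins))
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  n <- w[nbins]; mu_t <- mu[nbins]
  k <- seq_len(nbins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, nbins - 1L)
  sb[valid] <- (mu_t * w0[valid] - n * mu[k][valid])^2 /
    (w0[valid] * w1[valid])                       # n^2 * w0*w1*(mu0-mu1)^2
  best <- which.max(sb)                            # which.max takes the first tie
  breaks[best + 1L]
}

#' Cascaded (iterative) Otsu segmentation
#'
#' Step 1 thresholds all in-mask pixels; each later step re-runs
#' [otsu_threshold()] on the surviving foreground pixels only. The final
#' mask keeps the pixels above the last threshold, so masks are nested:
#' more steps never enlarge the foreground.
#'
#' @param image a [raster_image()].
#' @param steps number of cascade steps (1, 2 or 3). Two steps isolate the
#'   brightest of three populations (signal over marrow background over
#'   outside background).
#' @param within optional [binary_mask()] restricting the analysis.
#' @return a [binary_mask()] with attribute `thresholds` (one per executed
#'   step). If a step would leave fewer than 16 foreground pixels the
#'   cascade stops early with a warning and returns the last valid mask.
#' @export
iterative_otsu <- function(image, steps = 1L, within = NULL) {
  if (!steps %in% 1:3) stop("steps must be 1, 2 or 3")
  m <- as_plain(image)
  cur <- if (is.null(within)) matrix(TRUE, nrow(m), ncol(m)) else as_plain(within) > 0
  thresholds <- numeric(0)
  for (s in seq_len(steps)) {
    vals <- m[cur]
    if (sum(cur) < 16L) {
      warning(sprintf("cascade step %d: fewer than 16 pixels remain; stopping early", s))
      break
    }
    thr <- otsu_threshold(vals)
    nxt <- cur & m > thr
    if (sum(nxt) < 16L && s < steps) {
      warning(sprintf("cascade step %d leaves fewer than 16 foreground pixels; stopping early", s + 1L))
      cur <- nxt
      thresholds <- c(thresholds, thr)
      break
    }
    cur <- nxt
    thresholds <- c(thresholds, thr)
  }
  out <- binary_mask(cur, pixel_size(image))
  attr(out, "thresholds") <- thresholds
  out
}

# per-role cascade defaults: the mineral and label channels have two
# populations; TRAP/AP carry the additional marrow-space background
role_steps_default <- function() {
  c(mineral = 1L, label1 = 1L, label2 = 1L, dapi = 1L, gfp = 1L,
    trap = 2L, ap = 2L)
}

#' Segment one channel of a stack with its role defaults
#'
#' @param stack a channel stack.
#' @param role channel role present in the stack.
#' @param config optional list: `steps` (override cascade depth, logged in
#'   the returned mask's attributes), `shade` = list(enabled, window_um)
#'   applied before thresholding, `within` restriction mask.
#' @return a provenance-tagged [binary_mask()].
#' @export
segment_channel <- function(stack, role, config = list()) {
  ch <- stack$channels[[role]]
  if (is.null(ch)) stop(sprintf("channel role '%s' absent from stack", role))
  if (isTRUE(config$shade$enabled))
    ch <- shade_correct(ch, config$shade$window_um %||% 200,
                        config$shade$max_feature_um)
  steps <- config$steps %||% unname(role_steps_default()[role])
  if (is.na(steps)) steps <- 1L
  mask <- iterative_otsu(ch, steps = steps, within = config$within)
  attr(mask, "channel_role") <- role
  attr(mask, "steps") <- steps
  mask
}
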