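# Bone surface conditioning and region-of-interest selection.
#
# Scanned sections suffer ripped or chipped cortices; an elastic closed
# template initialized at the convex hull of the cortex is relaxed onto the
# bone contour under a curvature-smoothness penalty and used to bridge gaps,
# after which the endosteal cavity can be delineated and the analysis ROI
# placed relative to it.

#' Smooth the bone surface
#'
#' Median filter followed by morphological closing (dilation then erosion)
#' with a disk. The smoothed mask is intended only for surface/ROI geometry;
#' area measurements (BV/TV) use the raw segmentation.
#'
#' @param bone a [binary_mask()].
#' @param median_um median filter side length, micrometers.
#' @param close_um diameter of the closing disk, micrometers.
#' @return smoothed [binary_mask()].
#' @export
smooth_surface <- function(bone, median_um, close_um) {
  ps <- pixel_size(bone)
  m <- as_plain(bone) > 0
  mw <- um_to_px(median_um, ps)
  med <- if (mw >= 3L) {
    if (mw %% 2L == 0L) mw <- mw + 1L
    EBImage::medianFilter(m * 1.0, (mw - 1L) %/% 2L) > 0.5
  } else m
  cw <- max(1L, um_to_px(close_um, ps))
  if (cw %% 2L == 0L) cw <- cw + 1L
  if (cw >= 3L) {
    brush <- EBImage::makeBrush(cw, shape = "disc")
    med <- EBImage::closing(med, brush) > 0
  }
  binary_mask(med, ps, attr(bone, "channel_role"))
}

# components carrying at least `frac` of the largest component's area;
# the elastic template must not be captured by small trabecular islands
dominant_components <- function(mask, frac = 0.1) {
  lab <- EBImage::bwlabel(as_plain(mask) > 0)
  n <- max(lab)
  if (n == 0) return(NULL)
  sizes <- tabulate(lab[lab > 0], n)
  keep <- which(sizes >= frac * max(sizes))
  list(mask = matrix(lab %in% keep, nrow(mask), ncol(mask)), labels = lab,
       kept = keep, sizes = sizes)
}

# resample a closed polygon (n x 2 matrix of (x, y)) to k equal-arc-length
# nodes
resample_closed <- function(poly, k) {
  closed <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = k + 1)[-(k + 1)]
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[idx]) / pmax(seg[idx], 1e-12)
  closed[idx, , drop = FALSE] + frac * (closed[idx + 1, , drop = FALSE] -
                                        closed[idx, , drop = FALSE])
}

#' Repair broken cortices with an elastic contour template
#'
#' A closed elastic template (initialized as the convex hull of the dominant
#' cortical components, resampled to equal arc-length nodes) is iteratively
#' relaxed toward the bone contour: each node descends the distance
#' transform of the boundary while a curvature-smoothness term keeps the
#' chain coherent across gaps. After convergence, nodes that settled on the
#' contour are anchors; runs of unanchored nodes spanning a gap no wider
#' than `max_gap_um` are converted into thin bridges which are unioned onto
#' the mask. Bone pixels are never removed.
#'
#' @param bone a [binary_mask()] with a dominant outer component.
#' @param max_gap_um widest cortical gap to bridge, micrometers.
#' @param max_iter relaxation iteration cap (default 500); on
#'   non-convergence the best iterate is used with a warning.
#' @return repaired [binary_mask()]; attribute `bridges` holds the number of
#'   bridged gaps.
#' @export
repair_cortex <- function(bone, max_gap_um, max_iter = 500L) {
  ps <- pixel_size(bone)
  dom <- dominant_components(bone)
  if (is.null(dom)) stop("no outer component: bone mask is empty")
  m <- dom$mask
  bnd <- boundary_pixels(m)
  bpix <- which(bnd, arr.ind = TRUE)
  if (nrow(bpix) < 8) stop("no outer component: cortex boundary too small")
  # distance to the cortical boundary, used as the attraction field
  D <- EBImage::distmap(!bnd)
  gx <- matrix(0, nrow(D), ncol(D)); gy <- gx
  gx[, 2:(ncol(D) - 1)] <- (D[, 3:ncol(D)] - D[, 1:(ncol(D) - 2)]) / 2
  gy[2:(nrow(D) - 1), ] <- (D[3:nrow(D), ] - D[1:(nrow(D) - 2), ]) / 2

  pts <- cbind(x = bpix[, 2] - 1, y = bpix[, 1] - 1)
  hull <- pts[chull(pts), , drop = FALSE]
  per <- sum(sqrt(rowSums(diff(rbind(hull, hull[1, ]))^2)))
  k <- max(64L, as.integer(round(per / 2)))
  nodes <- resample_closed(hull, k)

  alpha <- 0.5   # attraction step along -grad(D)
  beta <- 0.25   # curvature smoothing toward neighbour mean
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- bilinear_sample(D, nodes[, 1], nodes[, 2], fill = max(D))
    sgx <- bilinear_sample(gx, nodes[, 1], nodes[, 2])
    sgy <- bilinear_sample(gy, nodes[, 1], nodes[, 2])
    norm <- pmax(sqrt(sgx^2 + sgy^2), 1e-9)
    step <- pmin(d, 1.5)                  # capped descent toward the contour
    attract <- -alpha * step * cbind(sgx, sgy) / norm
    prv <- rbind(nodes[nrow(nodes), ], nodes[-nrow(nodes), ])
    nxt <- rbind(nodes[-1, ], nodes[1, ])
    smooth <- beta * ((prv + nxt) / 2 - nodes)
    move <- attract + smooth
    nodes <- nodes + move
    if (max(abs(move)) < 0.05) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("elastic template did not converge in %d iterations; using best iterate", max_iter))

  d_final <- bilinear_sample(D, nodes[, 1], nodes[, 2], fill = max(D))
  anchored <- d_final <= 1.5
  out <- as_plain(bone) > 0
  nbridge <- 0L
  unbridged <- NULL
  if (any(!anchored) && any(anchored)) {
    # cyclic runs of unanchored nodes
    k <- length(anchored)
    idx <- seq_len(k)
    gap_id <- integer(k)
    cur <- 0L
    for (i in idx) if (!anchored[i]) {
      if (i == 1 || anchored[i - 1]) cur <- cur + 1L
      gap_id[i] <- cur
    }
    # merge a wrap-around gap
    if (!anchored[1] && !anchored[k] && cur > 1L)
      gap_id[gap_id == cur] <- gap_id[1]
    for (g in setdiff(unique(gap_id), 0L)) {
      seg <- which(gap_id == g)
      lo <- min(seg); hi <- max(seg)
      pre <- ifelse(lo > 1, lo - 1L, k)
      post <- ifelse(hi < k, hi + 1L, 1L)
      span_px <- sqrt(sum((nodes[pre, ] - nodes[post, ])^2))
      if (span_px * ps <= max_gap_um) {
        path <- nodes[c(pre, seg, post), , drop = FALSE]
        bridge <- draw_polyline(matrix(FALSE, nrow(out), ncol(out)), path,
                                width_px = 3)
        out <- out | bridge
        nbridge <- nbridge + 1L
      } else {
        unbridged <- rbind(unbridged, c(x = mean(nodes[seg, 1]),
                                        y = mean(nodes[seg, 2]),
                                        gap_um = span_px * ps))
      }
    }
    if (!is.null(unbridged))
      warning(sprintf("unbridged gap(s) wider than %g um at (x, y): %s",
                      max_gap_um,
                      paste(sprintf("(%.0f, %.0f; %.0f um)", unbridged[, 1],
                                    unbridged[, 2], unbridged[, 3]),
                            collapse = ", ")))
  }
  res <- binary_mask(out, ps, attr(bone, "channel_role"))
  attr(res, "bridges") <- nbridge
  res
}

# endosteal cavity of a (repaired) bone mask: the region enclosed by the
# dominant cortical components, excluding the cortex itself. Trabecular
# islands floating inside the cavity belong to the cavity region.
endosteal_cavity <- function(bone) {
  dom <- dominant_components(bone)
  if (is.null(dom)) stop("bone mask is empty")
  cortex <- dom$mask
  filled <- EBImage::fillHull(cortex) > 0
  cavity <- filled & !cortex
  list(cavity = cavity, cortex = cortex)
}

roi_mask <- function(pixels, pixel_size_um, site, tile_size_um = NA_real_) {
  out <- binary_mask(pixels, pixel_size_um)
  attr(out, "site") <- site
  attr(out, "tile_size_um") <- tile_size_um
  attr(out, "area_mm2") <- sum(pixels) * (pixel_size_um / 1000)^2
  class(out) <- c("roi_mask", class(out))
  out
}

#' Select the distal-femur region of interest
#'
#' The ROI starts `start_um` below the growth plate, stays at least
#' `inset_um` inside the endosteal surface, and is rasterized as a union of
#' `tile_um` x `tile_um` tiles following the endosteal contour. Tiles are
#' added row by row away from the growth plate until the target area is
#' reached; if the eligible interior is too small the achieved area is
#' returned with a warning.
#'
#' @param bone repaired [binary_mask()] (see [repair_cortex()]).
#' @param growth_plate_row 0-based row of the growth-plate bottom (required
#'   input; growth-plate detection is out of scope).
#' @param inset_um endosteal inset, default 250 (midpoint of the customary
#'   200-300 um range).
#' @param start_um distance below the growth plate where the ROI starts
#'   (default 400).
#' @param target_area_mm2 target ROI area (default 2.1).
#' @param tile_um ROI tile size (default 50).
#' @return an `roi_mask` with attributes `area_mm2`, `site`, `tile_size_um`.
#' @export
select_femur_roi <- function(bone, growth_plate_row, inset_um = 250,
                             start_um = 400, target_area_mm2 = 2.1,
                             tile_um = 50) {
  ps <- pixel_size(bone)
  if (growth_plate_row < 0 || growth_plate_row >= nrow(bone))
    stop("growth_plate_row outside image")
  cav <- endosteal_cavity(bone)
  if (!any(cav$cavity)) {
    warning("no interior cavity; returning empty ROI")
    return(roi_mask(matrix(FALSE, nrow(bone), ncol(bone)), ps, "femur", tile_um))
  }
  depth <- EBImage::distmap(cav$cavity) * ps
  start_row <- growth_plate_row + um_to_px(start_um, ps)
  rows0 <- matrix(0:(nrow(bone) - 1), nrow(bone), ncol(bone))
  eligible <- cav$cavity & depth >= inset_um & rows0 >= start_row
  tile_px <- max(1L, um_to_px(tile_um, ps))
  out <- matrix(FALSE, nrow(bone), ncol(bone))
  target_px <- target_area_mm2 / (ps / 1000)^2
  placed <- 0
  if (any(eligible)) {
    er <- range(which(rowSums(eligible) > 0))
    ec <- range(which(colSums(eligible) > 0))
    trows <- seq(er[1], er[2] - tile_px + 1, by = tile_px)
    tcols <- seq(ec[1], ec[2] - tile_px + 1, by = tile_px)
    for (tr in trows) {
      for (tc in tcols) {
        if (placed >= target_px) break
        block <- eligible[tr:(tr + tile_px - 1), tc:(tc + tile_px - 1)]
        if (all(block)) {
          out[tr:(tr + tile_px - 1), tc:(tc + tile_px - 1)] <- TRUE
          placed <- placed + tile_px^2
        }
      }
      if (placed >= target_px) break
    }
  }
  if (placed < target_px * 0.85)
    warning(sprintf("eligible interior supports only %.2f mm2 of the %.2f mm2 target",
                    placed * (ps / 1000)^2, target_area_mm2))
  roi_mask(out, ps, "femur", tile_um)
}

#' Select the vertebral region of interest
#'
#' The ROI is the central region enclosed by the offset contour `band_um`
#' inside the endosteal surface of the vertebral body: cavity pixels whose
#' endosteal depth is at least `band_um`. With `mode = "band"` the
#' complementary peri-endosteal reading (depth up to `band_um`) is selected
#' instead.
#'
#' @param bone repaired [binary_mask()].
#' @param band_um endosteal offset, default 770.
#' @param mode "central" (default) or "band".
#' @return an `roi_mask`; errors if the offset contour is empty (band wider
#'   than half the cavity).
#' @export
select_vertebra_roi <- function(bone, band_um = 770, mode = c("central", "band")) {
  mode <- match.arg(mode)
  ps <- pixel_size(bone)
  cav <- endosteal_cavity(bone)
  if (!any(cav$cavity)) stop("no interior cavity in vertebra mask")
  depth <- EBImage::distmap(cav$cavity) * ps
  out <- if (mode == "central") cav$cavity & depth >= band_um
         else cav$cavity & depth < band_um & depth > 0
  if (!any(out))
    stop(sprintf("offset contour empty: %g um exceeds half the cavity width", band_um))
  roi_mask(out, ps, "vertebra")
}
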