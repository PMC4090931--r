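# Fiducial-bead registration: calibrated 6 um fluorescent beads spotted next
# to the section are detected in the reference (mineral/label) scan and in
# the TRAP/AP stain scans; a least-squares similarity transform (rotation,
# isotropic scale, translation — no reflection) maps the stain scans onto
# the reference grid. Landmarks give rotation and the tape-shrinkage scale
# directly, so the fit is closed-form.

#' Similarity transform
#'
#' Maps moving-scan coordinates onto the reference scan:
#' `x_ref = scale * R(rotation) * x_mov + (dx, dy)`, with x = (col, row) in
#' 0-based pixel units and rotation positive from +x toward +y (downward
#' row axis).
#'
#' @param rotation_deg rotation angle in degrees.
#' @param scale isotropic scale (> 0).
#' @param dx,dy translation in pixels.
#' @param rmse_px fit residual (root-mean-square centroid distance).
#' @return a `similarity_transform`.
#' @export
similarity_transform <- function(rotation_deg = 0, scale = 1, dx = 0, dy = 0,
                                 rmse_px = 0) {
  if (scale <= 0) stop("scale must be > 0")
  if (rmse_px < 0) stop("rmse_px must be >= 0")
  structure(list(rotation_deg = rotation_deg, scale = scale,
                 dx = dx, dy = dy, rmse_px = rmse_px),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> rot %.3f deg, scale %.4f, shift (%.2f, %.2f) px, rmse %.3f px\n",
              x$rotation_deg, x$scale, x$dx, x$dy, x$rmse_px))
  invisible(x)
}

# apply transform to an n x 2 matrix of (x, y) points
tf_apply <- function(tf, xy) {
  th <- deg2rad(tf$rotation_deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(tf$scale * (xy %*% t(R)), 2, c(tf$dx, tf$dy), `+`)
}

tf_inverse <- function(tf) {
  th <- -deg2rad(tf$rotation_deg)
  s <- 1 / tf$scale
  t0 <- -s * c(cos(th) * tf$dx - sin(th) * tf$dy,
               sin(th) * tf$dx + cos(th) * tf$dy)
  similarity_transform(-tf$rotation_deg, s, t0[1], t0[2])
}

tf_compose <- function(a, b) {
  # returns transform equivalent to applying b first, then a
  tb <- tf_apply(a, matrix(c(b$dx, b$dy), 1))
  similarity_transform(a$rotation_deg + b$rotation_deg, a$scale * b$scale,
                       tb[1], tb[2])
}

#' Build a transform that pivots about a given center
#'
#' Convenience constructor: rotation/scale about `center` followed by a
#' shift, expressed in the origin-pivot parameterization of
#' [similarity_transform()].
#'
#' @param rotation_deg,scale,dx,dy transform parameters.
#' @param center (x, y) pivot in pixels.
#' @export
similarity_about_center <- function(rotation_deg, scale, dx, dy, center) {
  th <- deg2rad(rotation_deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t0 <- center - scale * (R %*% center) + c(dx, dy)
  similarity_transform(rotation_deg, scale, t0[1], t0[2])
}

#' Detect fiducial beads
#'
#' Thresholds the image (two-class Otsu), labels connected bright components
#' and keeps those whose equivalent diameter is within +/- 50 percent of the
#' expected bead diameter and whose solidity (area over convex-hull area) is
#' at least 0.8. Centroids are intensity-weighted.
#'
#' @param image a [raster_image()].
#' @param expected_diameter_um expected bead diameter (6 um calibrated
#'   beads); must exceed 2 px at the image's pixel size.
#' @param steps Otsu cascade depth for the binarization; use 2 for channels
#'   carrying a marrow-background population (TRAP/AP stain scans), 1 for
#'   the label channels.
#' @return a `bead_set` data.frame with columns x, y (0-based px) and
#'   diameter_um; may be empty.
#' @export
detect_beads <- function(image, expected_diameter_um = 6, steps = 1L) {
  ps <- pixel_size(image)
  exp_px <- expected_diameter_um / ps
  if (exp_px <= 2) stop("expected bead diameter must exceed 2 px; use a finer pixel size")
  m <- as_plain(image)
  empty <- data.frame(x = numeric(0), y = numeric(0), diameter_um = numeric(0))
  if (diff(range(m)) == 0)
    return(structure(empty, class = c("bead_set", "data.frame"),
                     pixel_size_um = ps))
  lab <- EBImage::bwlabel(as_plain(iterative_otsu(image, steps = steps)))
  n <- max(lab)
  out <- NULL
  for (i in seq_len(n)) {
    idx <- which(lab == i, arr.ind = TRUE)
    area <- nrow(idx)
    eq_d <- 2 * sqrt(area / pi)
    if (abs(eq_d - exp_px) > 0.5 * exp_px) next
    # solidity via convex hull of pixel centers (Pick-style area correction
    # for the half-pixel border of small components)
    xy <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
    if (area >= 3) {
      h <- chull(xy)
      hull_area <- polygon_area(xy[h, , drop = FALSE]) +
        nrow(xy[h, , drop = FALSE]) / 2 + 1
      if (area / hull_area < 0.8) next
    }
    w <- m[idx]
    out <- rbind(out, data.frame(x = sum(w * xy[, 1]) / sum(w),
                                 y = sum(w * xy[, 2]) / sum(w),
                                 diameter_um = eq_d * ps))
  }
  out <- out %||% empty
  structure(out, class = c("bead_set", "data.frame"), pixel_size_um = ps)
}

#' Match beads between the reference and a moving scan
#'
#' Both centroid clouds are centered and coarsely aligned by their principal
#' axes (the residual rotation between scans is small, well under 45
#' degrees), then mutually nearest pairs are kept. Unmatched beads are
#' dropped.
#'
#' @param reference,moving bead sets ([detect_beads()]) with >= 2 beads each.
#' @return data.frame of pair indices (ref, mov) with the paired
#'   coordinates.
#' @export
match_beads <- function(reference, moving) {
  if (nrow(reference) < 2 || nrow(moving) < 2)
    stop("insufficient fiducials: each bead set needs >= 2 beads")
  P <- as.matrix(reference[, c("x", "y")])
  Q <- as.matrix(moving[, c("x", "y")])
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  ang <- function(X) {
    e <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
    atan2(e$vectors[2, 1], e$vectors[1, 1])
  }
  d <- ang(Pc) - ang(Qc)
  d <- atan2(sin(d), cos(d))                  # wrap to (-pi, pi]
  if (d > pi / 2) d <- d - pi                 # principal axis is mod 180 deg
  if (d < -pi / 2) d <- d + pi
  # the principal axis of a near-isotropic cloud is noise-driven; try both
  # the PCA angle and no coarse rotation and keep the better pairing
  mutual_pairs <- function(delta) {
    R <- matrix(c(cos(delta), sin(delta), -sin(delta), cos(delta)), 2, 2)
    Qr <- Qc %*% t(R)
    D <- outer(rowSums(Pc^2), rowSums(Qr^2), `+`) - 2 * Pc %*% t(Qr)
    nn_pq <- apply(D, 1, which.min)
    nn_qp <- apply(D, 2, which.min)
    mutual <- which(nn_qp[nn_pq] == seq_len(nrow(P)))
    list(pairs = data.frame(ref = mutual, mov = nn_pq[mutual]),
         score = if (length(mutual))
           sum(D[cbind(mutual, nn_pq[mutual])]) / length(mutual)^2 else Inf)
  }
  cand <- lapply(unique(c(d, 0)), mutual_pairs)
  pairs <- cand[[which.min(vapply(cand, `[[`, numeric(1), "score"))]]$pairs
  if (nrow(pairs) < 2)
    stop("insufficient fiducials: fewer than 2 mutually nearest pairs")
  cbind(pairs,
        ref_x = P[pairs$ref, 1], ref_y = P[pairs$ref, 2],
        mov_x = Q[pairs$mov, 1], mov_y = Q[pairs$mov, 2])
}

#' Least-squares similarity transform from bead correspondences
#'
#' Closed-form fit (complex-plane Procrustes, reflection-free) of rotation,
#' isotropic scale and translation minimizing the sum of squared centroid
#' distances `|x_ref - (s R x_mov + t)|^2`.
#'
#' @param pairs correspondence data.frame from [match_beads()] (columns
#'   ref_x, ref_y, mov_x, mov_y), >= 2 non-coincident pairs.
#' @return a [similarity_transform()] with `rmse_px` filled in.
#' @export
estimate_similarity <- function(pairs) {
  if (nrow(pairs) < 2) stop("need >= 2 correspondences")
  p <- complex(real = pairs$ref_x, imaginary = pairs$ref_y)
  q <- complex(real = pairs$mov_x, imaginary = pairs$mov_y)
  qc <- q - mean(q); pc <- p - mean(p)
  denom <- sum(Mod(qc)^2)
  if (denom < 1e-12)
    stop("degenerate bead cloud: moving centroids are coincident")
  a <- sum(pc * Conj(qc)) / denom
  t <- mean(p) - a * mean(q)
  fit <- a * q + t
  rmse <- sqrt(mean(Mod(p - fit)^2))
  similarity_transform(rotation_deg = rad2deg(Arg(a)), scale = Mod(a),
                       dx = Re(t), dy = Im(t), rmse_px = rmse)
}

#' Resample moving channels onto the reference grid
#'
#' Each listed channel is warped with the inverse transform and bilinear
#' interpolation; pixels mapping outside the moving field are zero-filled
#' and recorded in a validity mask.
#'
#' @param stack a channel stack whose listed channels live on the moving
#'   (stain scan) grid.
#' @param transform the moving-to-reference [similarity_transform()].
#' @param channels channel roles to warp (default trap/ap when present).
#' @return the stack with listed channels resampled; attribute
#'   `validity_mask` marks in-field pixels.
#' @export
warp_to_reference <- function(stack, transform,
                              channels = intersect(c("trap", "ap"),
                                                   names(stack$channels))) {
  stopifnot(inherits(transform, "similarity_transform"))
  inv <- tf_inverse(transform)
  valid <- NULL
  for (role in channels) {
    ch <- stack$channels[[role]]
    nr <- nrow(ch); nc <- ncol(ch)
    grid_x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    grid_y <- matrix(0:(nr - 1), nr, nc)
    src <- tf_apply(inv, cbind(as.vector(grid_x), as.vector(grid_y)))
    vals <- bilinear_sample(as_plain(ch), src[, 1], src[, 2], fill = 0)
    stack$channels[[role]] <- raster_image(matrix(vals, nr, nc), pixel_size(ch))
    if (is.null(valid)) {
      inb <- src[, 1] >= 0 & src[, 1] <= nc - 1 & src[, 2] >= 0 & src[, 2] <= nr - 1
      valid <- matrix(inb, nr, nc)
    }
  }
  attr(stack, "validity_mask") <- valid
  attr(stack, "applied_transform") <- transform
  stack
}

#' Serialize / deserialize a similarity transform as JSON
#' @param transform a [similarity_transform()].
#' @param path output path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(x$rotation_deg, x$scale, x$dx, x$dy, x$rmse_px %||% 0)
}
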