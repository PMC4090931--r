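# Shared low-level helpers: raster/mask constructors, unit conversion,
# sampling and small drawing primitives used by the phantom generator.

#' Create a raster image
#'
#' A raster image is a numeric matrix of non-negative intensities carrying a
#' physical pixel size. Pixel size is always explicit user input; it is never
#' inferred from file metadata because every physical threshold in the
#' analysis (25.6 um cell proximity, 400 um ROI offset, ...) depends on it.
#'
#' @param pixels numeric matrix, at least 2 x 2, non-negative intensities.
#' @param pixel_size_um physical size of one pixel in micrometers (> 0).
#' @return a `raster_image` (matrix with `pixel_size_um` attribute).
#' @export
raster_image <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("raster must be at least 2 x 2")
  if (anyNA(pixels) || any(pixels < 0))
    stop("intensities must be non-negative and finite")
  check_pixel_size(pixel_size_um)
  structure(pixels, pixel_size_um = as.numeric(pixel_size_um),
            class = c("raster_image", class(pixels)))
}

check_pixel_size <- function(pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  invisible(pixel_size_um)
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), pixel_size(x), min(x), max(x)))
  invisible(x)
}

#' Pixel size accessor
#' @param x a raster_image, binary_mask or channel_stack.
#' @return pixel size in micrometers per pixel.
#' @export
pixel_size <- function(x) {
  ps <- if (is.list(x) && !is.null(x$pixel_size_um)) x$pixel_size_um
        else attr(x, "pixel_size_um")
  if (is.null(ps)) stop("object carries no pixel_size_um")
  ps
}

#' Create a binary mask
#'
#' @param pixels logical matrix.
#' @param pixel_size_um micrometers per pixel.
#' @param channel_role optional provenance tag (source channel role).
#' @return a `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size_um, channel_role = NULL) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (!is.logical(pixels)) {
    pixels <- pixels > 0
  }
  check_pixel_size(pixel_size_um)
  structure(pixels, pixel_size_um = as.numeric(pixel_size_um),
            channel_role = channel_role,
            class = c("binary_mask", class(pixels)))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g um/px, %d foreground px (%s)\n",
              nrow(x), ncol(x), pixel_size(x), sum(x),
              attr(x, "channel_role") %||% "untagged"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip classes/attributes down to a plain matrix
as_plain <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x))
  y
}

um_to_px <- function(um, pixel_size_um) as.integer(round(um / pixel_size_um))

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Bilinear sampling of matrix m at 0-based (x = col, y = row) coordinates.
# Points outside the grid return `fill`.
bilinear_sample <- function(m, x, y, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  out <- rep(fill, length(x))
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1
  # clamp the upper sample for points on the last row/col
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  if (any(ok)) {
    i00 <- cbind(y0[ok] + 1, x0[ok] + 1)
    i01 <- cbind(y0[ok] + 1, x1[ok] + 1)
    i10 <- cbind(y1[ok] + 1, x0[ok] + 1)
    i11 <- cbind(y1[ok] + 1, x1[ok] + 1)
    v <- (1 - fx[ok]) * (1 - fy[ok]) * m[i00] +
         fx[ok] * (1 - fy[ok]) * m[i01] +
         (1 - fx[ok]) * fy[ok] * m[i10] +
         fx[ok] * fy[ok] * m[i11]
    out[ok] <- v
  }
  out
}

# Paint a filled disk (0-based center, radius in px) into matrix m.
draw_disk <- function(m, cx, cy, radius_px, value) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- max(0, floor(cy - radius_px)); r1 <- min(nr - 1, ceiling(cy + radius_px))
  c0 <- max(0, floor(cx - radius_px)); c1 <- min(nc - 1, ceiling(cx + radius_px))
  if (r0 > r1 || c0 > c1) return(m)
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - cy, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cx)
  hit <- dr * dr + dc * dc <= radius_px^2
  sub <- m[rows + 1, cols + 1, drop = FALSE]
  sub[hit] <- value
  m[rows + 1, cols + 1] <- sub
  m
}

# Paint a polyline (matrix of 0-based (x, y) vertices) of given width into a
# logical mask.
draw_polyline <- function(mask, xy, width_px = 1) {
  pts <- NULL
  for (i in seq_len(nrow(xy) - 1)) {
    p0 <- xy[i, ]; p1 <- xy[i + 1, ]
    n <- max(2L, ceiling(2 * sqrt(sum((p1 - p0)^2))))
    t <- seq(0, 1, length.out = n)
    pts <- rbind(pts, cbind(p0[1] + t * (p1[1] - p0[1]),
                            p0[2] + t * (p1[2] - p0[2])))
  }
  rr <- round(pts[, 2]); cc <- round(pts[, 1])
  keep <- rr >= 0 & cc >= 0 & rr < nrow(mask) & cc < ncol(mask)
  mask[cbind(rr[keep] + 1, cc[keep] + 1)] <- TRUE
  if (width_px > 1) {
    brush <- EBImage::makeBrush(ifelse(width_px %% 2 == 1, width_px, width_px + 1),
                                shape = "box")
    mask <- EBImage::dilate(mask, brush) > 0
  }
  mask
}

# 4-connected boundary pixels of a logical mask (bone pixels adjacent to
# background or to the image border).
boundary_pixels <- function(mask) {
  m <- as_plain(mask) > 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  m & !interior
}

# Polygon area (shoelace) for a matrix of (x, y) vertices.
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Even-odd ray-cast point-in-polygon test (vectorized over points).
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# run a block with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
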