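# Tile stitching by k-th law nonlinear correlation.
#
# The cross-power spectrum of two tiles is computed in the Fourier domain and
# its magnitude is raised to the exponent k in [0, 1] before inverse
# transformation: k = 1 keeps the full magnitude weighting (classical
# cross-correlation), k = 0 discards magnitude entirely (pure phase
# correlation), and intermediate k balances intensity against phase/outline
# information. k = 0.3 is the working default.

#' Tile grid container
#'
#' @param tiles list of tile matrices, row-major over the grid.
#' @param grid_shape integer (rows, cols) of the grid.
#' @param tile_shape integer (rows, cols) of each tile.
#' @param nominal_overlap nominal overlap fraction of adjacent tiles.
#' @param pixel_size_um micrometers per pixel.
#' @return a `tile_grid`.
#' @export
tile_grid <- function(tiles, grid_shape, tile_shape, nominal_overlap,
                      pixel_size_um = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(tiles) != prod(grid_shape))
    stop("number of tiles does not match grid_shape")
  for (t in tiles)
    if (!identical(dim(t), as.integer(tile_shape)))
      stop("all tiles must share tile_shape")
  structure(list(tiles = tiles, grid_shape = grid_shape,
                 tile_shape = as.integer(tile_shape),
                 nominal_overlap = nominal_overlap,
                 pixel_size_um = pixel_size_um),
            class = "tile_grid")
}

grid_tile <- function(grid, r, c) grid$tiles[[(r - 1L) * grid$grid_shape[2] + c]]

#' k-th law nonlinear cross-correlation of two equally shaped images
#'
#' Returns the inverse FFT of the cross-power spectrum whose magnitude is
#' raised to the power k. The peak of the surface sits at the cyclic shift s
#' with `b(p) = a(p + s)`; the reported peak resolves FFT wrap-around to the
#' signed shift of smallest magnitude.
#'
#' @param a,b numeric matrices of identical shape.
#' @param k exponent in [0, 1] (0 = phase correlation, 1 = classical
#'   cross-correlation weighting).
#' @param eps magnitude floor before exponentiation, guards zero-energy
#'   frequencies.
#' @return list with `surface` (correlation surface), `peak = c(dy, dx)`
#'   signed shift, `peak_score` (peak-to-RMS ratio of the surface) and
#'   `degenerate` flag.
#' @export
kth_law_correlate <- function(a, b, k, eps = 1e-12) {
  a <- as_plain(a); b <- as_plain(b)
  if (!identical(dim(a), dim(b))) stop("a and b must share shape")
  if (k < 0 || k > 1) stop("k must lie in [0, 1]")
  Fa <- fft(a); Fb <- fft(b)
  C <- Fa * Conj(Fb)
  mag <- Mod(C)
  degenerate <- all(mag < eps)
  Ck <- C * pmax(mag, eps)^(k - 1)
  surf <- Re(fft(Ck, inverse = TRUE)) / length(Ck)
  if (degenerate) {
    return(list(surface = surf, peak = c(dy = 0L, dx = 0L),
                peak_score = 0, degenerate = TRUE))
  }
  idx <- which.max(surf)
  pr <- (idx - 1L) %% nrow(surf)
  pc <- (idx - 1L) %/% nrow(surf)
  wrap <- function(v, n) if (v > n / 2) v - n else v
  peak <- c(dy = wrap(pr, nrow(surf)), dx = wrap(pc, ncol(surf)))
  rms <- sqrt(mean(surf^2))
  list(surface = surf, peak = peak,
       peak_score = if (rms > 0) max(surf) / rms else 0,
       degenerate = FALSE)
}

# wrapped lookup of the correlation surface at signed shifts (vectorized)
surf_at <- function(surf, dy, dx) {
  surf[cbind((dy %% nrow(surf)) + 1L, (dx %% ncol(surf)) + 1L)]
}

#' Estimate the offset between two adjacent overlapping tiles
#'
#' Correlates the two tiles and searches the peak only inside the window of
#' offsets consistent with the expected overlap +/- 50 percent (along the
#' adjacency axis; the transverse misalignment window is half the overlap
#' width). The returned offset is the 0-based placement of the second tile's
#' origin in the first tile's frame.
#'
#' @param left,right adjacent tiles; `right` lies to the right of (or below,
#'   see `direction`) `left`.
#' @param k correlation exponent, default 0.3.
#' @param expected_overlap expected overlap fraction in [0.05, 0.5].
#' @param direction "right" or "down" adjacency.
#' @param min_score peak-to-RMS floor under which the overlap is declared
#'   unreliable.
#' @return a `translation`: list(dy, dx, peak_score).
#' @export
estimate_overlap_offset <- function(left, right, k = 0.3, expected_overlap,
                                    direction = c("right", "down"),
                                    min_score = 5) {
  direction <- match.arg(direction)
  if (expected_overlap < 0.05 || expected_overlap > 0.5)
    stop("expected_overlap must lie in [0.05, 0.5]")
  cc <- kth_law_correlate(left, right, k)
  if (cc$degenerate) stop("no reliable overlap: degenerate (all-zero) input")
  nr <- nrow(left); nc <- ncol(left)
  if (direction == "right") {
    ow <- expected_overlap * nc
    dxs <- seq.int(max(1L, floor(nc - 1.5 * ow)), min(nc - 1L, ceiling(nc - 0.5 * ow)))
    dys <- seq.int(-ceiling(0.5 * expected_overlap * nr),
                   ceiling(0.5 * expected_overlap * nr))
  } else {
    ow <- expected_overlap * nr
    dys <- seq.int(max(1L, floor(nr - 1.5 * ow)), min(nr - 1L, ceiling(nr - 0.5 * ow)))
    dxs <- seq.int(-ceiling(0.5 * expected_overlap * nc),
                   ceiling(0.5 * expected_overlap * nc))
  }
  win <- expand.grid(dy = dys, dx = dxs)
  vals <- surf_at(cc$surface, win$dy, win$dx)
  best <- which.max(vals)
  rms <- sqrt(mean(cc$surface^2))
  score <- if (rms > 0) vals[best] / rms else 0
  if (!is.finite(score) || score < min_score)
    stop(sprintf("no reliable overlap: peak score %.2f below floor %.2f",
                 score, min_score))
  structure(list(dy = win$dy[best], dx = win$dx[best], peak_score = score),
            class = "translation")
}

#' Assemble a tile grid into a whole-section image
#'
#' Pairwise offsets are estimated for horizontal neighbours within each grid
#' row and for vertical neighbours along the first column, then chained
#' row-then-column into global placements. Overlap pixels keep the
#' first-placed tile's values. Loop closure is checked on every 2x2 grid
#' cell: row-path and column-path placements disagreeing by more than 2 px
#' raise a warning, by more than 10 px an error.
#'
#' @param grid a [tile_grid()].
#' @param k correlation exponent (default 0.3).
#' @param min_score reliability floor, see [estimate_overlap_offset()].
#' @return assembled [raster_image()] with attribute `tile_offsets` (0-based
#'   global placements).
#' @export
assemble_tiles <- function(grid, k = 0.3, min_score = 5) {
  stopifnot(inherits(grid, "tile_grid"))
  gr <- grid$grid_shape[1]; gc <- grid$grid_shape[2]
  ov <- grid$nominal_overlap
  for (r in seq_len(gr)) for (c in seq_len(gc)) {
    if (all(grid_tile(grid, r, c) == 0))
      stop(sprintf("degenerate all-zero tile at grid position (%d, %d)", r, c))
  }
  if (gr == 1L && gc == 1L) {
    out <- raster_image(grid_tile(grid, 1, 1) * 1.0, grid$pixel_size_um)
    attr(out, "tile_offsets") <- cbind(grid_row = 1, grid_col = 1, row0 = 0, col0 = 0)
    return(out)
  }
  pos <- array(NA_real_, dim = c(gr, gc, 2))  # (row0, col0)
  pos[1, 1, ] <- c(0, 0)
  right_off <- array(NA_real_, dim = c(gr, gc, 2))
  down_off <- array(NA_real_, dim = c(gr, gc, 2))
  for (r in seq_len(gr)) {
    if (r > 1) {
      tr <- estimate_overlap_offset(grid_tile(grid, r - 1, 1), grid_tile(grid, r, 1),
                                    k, ov, "down", min_score)
      down_off[r - 1, 1, ] <- c(tr$dy, tr$dx)
      pos[r, 1, ] <- pos[r - 1, 1, ] + c(tr$dy, tr$dx)
    }
    for (c in seq_len(gc)[-1]) {
      tr <- estimate_overlap_offset(grid_tile(grid, r, c - 1), grid_tile(grid, r, c),
                                    k, ov, "right", min_score)
      right_off[r, c - 1, ] <- c(tr$dy, tr$dx)
      pos[r, c, ] <- pos[r, c - 1, ] + c(tr$dy, tr$dx)
    }
  }
  # loop closure: compare chained row-path position against the column path
  if (gr > 1 && gc > 1) {
    for (r in seq_len(gr)[-1]) for (c in seq_len(gc)[-1]) {
      tr <- estimate_overlap_offset(grid_tile(grid, r - 1, c), grid_tile(grid, r, c),
                                    k, ov, "down", min_score)
      alt <- pos[r - 1, c, ] + c(tr$dy, tr$dx)
      disc <- max(abs(alt - pos[r, c, ]))
      if (disc > 10)
        stop(sprintf("loop closure failure at grid (%d, %d): %g px", r, c, disc))
      if (disc > 2)
        warning(sprintf("loop closure discrepancy at grid (%d, %d): %g px", r, c, disc))
    }
  }
  pos[, , 1] <- pos[, , 1] - min(pos[, , 1])
  pos[, , 2] <- pos[, , 2] - min(pos[, , 2])
  H <- max(pos[, , 1]) + grid$tile_shape[1]
  W <- max(pos[, , 2]) + grid$tile_shape[2]
  canvas <- matrix(NA_real_, H, W)
  offsets <- NULL
  for (r in seq_len(gr)) for (c in seq_len(gc)) {
    r0 <- pos[r, c, 1]; c0 <- pos[r, c, 2]
    rows <- r0 + seq_len(grid$tile_shape[1])
    cols <- c0 + seq_len(grid$tile_shape[2])
    sub <- canvas[rows, cols, drop = FALSE]
    tile <- grid_tile(grid, r, c)
    sub[is.na(sub)] <- tile[is.na(sub)]     # first-placed tile wins
    canvas[rows, cols] <- sub
    offsets <- rbind(offsets, c(grid_row = r, grid_col = c, row0 = r0, col0 = c0))
  }
  canvas[is.na(canvas)] <- 0
  out <- raster_image(canvas, grid$pixel_size_um)
  attr(out, "tile_offsets") <- offsets
  out
}
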