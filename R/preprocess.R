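# Shade correction: slowly varying illumination gradients are estimated with
# a large-window median filter and subtracted. The window must be larger
# than the largest trabecular feature, otherwise bone structures leak into
# the background estimate and are erased by the subtraction.

#' Shade-correct an image by median-filter background subtraction
#'
#' `output = clip(input - median_filter(input, window), 0, max)`, with
#' reflective border handling. Besides flattening illumination ramps this
#' also removes minor background offsets, so the corrected background
#' median is approximately zero.
#'
#' @param image a [raster_image()].
#' @param window_um median filter side length in micrometers; must exceed
#'   the largest trabecular feature size (a warning is issued when
#'   `max_feature_um` is given and violated). Rounded to an odd pixel count
#'   of at least 3.
#' @param max_feature_um optional configured size of the largest trabecular
#'   feature, used for the precondition check.
#' @return shade-corrected [raster_image()].
#' @export
shade_correct <- function(image, window_um, max_feature_um = NULL) {
  ps <- pixel_size(image)
  w <- max(3L, as.integer(round(window_um / ps)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w >= min(dim(image)))
    stop("shade-correction window must be smaller than the image")
  if (!is.null(max_feature_um) && window_um <= max_feature_um)
    warning(sprintf(
      "shade window (%g um) does not exceed the largest feature size (%g um); bone structures may be attenuated",
      window_um, max_feature_um))
  m <- as_plain(image)
  r <- (w - 1L) %/% 2L
  # reflective padding; EBImage's median filter operates on [0, 1]
  pad <- m[c(seq(r + 1, 2, -1), seq_len(nrow(m)), seq(nrow(m) - 1, nrow(m) - r, -1)),
           c(seq(r + 1, 2, -1), seq_len(ncol(m)), seq(ncol(m) - 1, ncol(m) - r, -1)),
           drop = FALSE]
  top <- max(pad, 1)
  med <- EBImage::medianFilter(pad / top, r) * top
  med <- med[r + seq_len(nrow(m)), r + seq_len(ncol(m)), drop = FALSE]
  raster_image(pmax(m - med, 0), ps)
}
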