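# Channel image I/O and the validated co-registered stack.

#' Read a single-channel image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG file. Multi-channel (color)
#' files are rejected: each fluorescence role must live in its own file,
#' mirroring per-filter microscope scans. Integer sample values are preserved
#' losslessly (TIFF); PNG samples are rescaled to their integer bit range.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param pixel_size_um micrometers per pixel (mandatory; never inferred from
#'   file metadata).
#' @return a [raster_image()].
#' @export
read_channel <- function(path, pixel_size_um) {
  check_pixel_size(pixel_size_um)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    m <- png::readPNG(path)
    if (is.matrix(m)) m <- round(m * 65535)
  } else {
    stop(sprintf("unsupported image format '%s' (use grayscale TIFF or PNG)", ext))
  }
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] == 1L) m <- m[, , 1]
    else stop(sprintf("'%s' is a multi-channel color file; channel roles must be separate grayscale files", path))
  }
  raster_image(m * 1.0, pixel_size_um)
}

#' Write a single-channel image
#'
#' Writes a grayscale TIFF with 8 or 16 bits per sample. Writing then
#' reading with [read_channel()] is bit-exact for integer intensities within
#' the bit range.
#'
#' @param image raster image or matrix of integers.
#' @param path output .tif/.tiff path.
#' @param bits 8 or 16.
#' @export
write_channel <- function(image, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  m <- as_plain(image)
  top <- 2^bits - 1
  if (any(m < 0) || any(m > top) || any(m != round(m)))
    stop(sprintf("intensities must be integers in [0, %d] for %d-bit output", top, bits))
  tiff::writeTIFF(m / top, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Assemble channel images into a validated stack
#'
#' @param images named list of [raster_image()] keyed by role; roles from
#'   mineral, label1, label2, trap, ap, dapi, gfp. The mineral channel is
#'   mandatory; all channels must share shape and pixel size.
#' @param site bone site, "femur" or "vertebra".
#' @return a `channel_stack`.
#' @export
build_stack <- function(images, site = c("femur", "vertebra")) {
  site <- match.arg(site)
  roles <- c("mineral", "label1", "label2", "trap", "ap", "dapi", "gfp")
  if (is.null(names(images)) || !all(nzchar(names(images))))
    stop("images must be a named list keyed by channel role")
  unknown <- setdiff(names(images), roles)
  if (length(unknown))
    stop(sprintf("unknown channel role(s): %s", paste(unknown, collapse = ", ")))
  if (!"mineral" %in% names(images)) stop("the mineral channel is mandatory")
  ref <- images[["mineral"]]
  ps <- pixel_size(ref)
  for (role in names(images)) {
    im <- images[[role]]
    if (!identical(dim(im), dim(ref)))
      stop(sprintf("channel '%s' shape (%d x %d) does not match mineral (%d x %d)",
                   role, nrow(im), ncol(im), nrow(ref), ncol(ref)))
    if (abs(pixel_size(im) - ps) > 1e-12)
      stop(sprintf("channel '%s' pixel size differs from mineral", role))
  }
  structure(list(channels = images, site = site, pixel_size_um = ps),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %s, %d x %d px at %.4g um/px; channels: %s\n",
              x$site, nrow(x$channels[[1]]), ncol(x$channels[[1]]),
              x$pixel_size_um, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write a channel stack to a directory
#'
#' One 16-bit grayscale TIFF per channel role plus a `stack.json` metadata
#' document (site, pixel size, channel file names).
#'
#' @param stack a channel stack.
#' @param dir output directory (created if needed).
#' @return invisibly, the metadata list.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (role in names(stack$channels)) {
    f <- file.path(dir, paste0(role, ".tiff"))
    write_channel(round(as_plain(stack$channels[[role]])), f)
    files[[role]] <- basename(f)
  }
  meta <- list(site = stack$site, pixel_size_um = stack$pixel_size_um,
               channels = files)
  jsonlite::write_json(meta, file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(meta)
}

#' Read a channel stack written by [write_stack()]
#' @param dir directory containing `stack.json` and the channel TIFFs.
#' @return a `channel_stack`.
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  imgs <- lapply(meta$channels, function(f)
    read_channel(file.path(dir, f), meta$pixel_size_um))
  build_stack(imgs, site = meta$site)
}

# canonical measurement schema: field name -> units
report_schema <- function() {
  c(bv_tv = "%", tb_th = "um", tb_n = "/mm", tb_sp = "um",
    l2_bs = "%", l1_bs = "%", l2_only_bs = "%", l1_only_bs = "%",
    sls_bs = "%", dls_bs = "%", ls_bs = "%", ms_bs = "%",
    sls_ls = "%", dls_ls = "%", dls_sls = "%",
    ir_l_th = "um", mar = "um/day", bfr = "um3/um2/day",
    ap_bs = "%", ap_l2_bs = "%", ap_only_bs = "%",
    trap_bs = "%", trap_l2_bs = "%", trap_only_bs = "%",
    trap_tv = "%", trap_on_trap = "%")
}

#' Write a histomorphometry report
#'
#' Emits every measurement with name, value and units. Measurements that are
#' undefined for the section (for example ratios with an empty denominator)
#' are serialized as null (JSON) / empty (CSV), never as zero: "no labeled
#' surface" and "zero fraction" are different findings.
#'
#' @param report a `histomorphometry_report` (see [build_report()]).
#' @param path output file path.
#' @param format "json" or "csv".
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "histomorphometry_report"))
  schema <- report_schema()
  vals <- report_values(report)
  if (format == "json") {
    doc <- list(
      measurements = lapply(names(schema), function(nm)
        list(name = nm, value = vals[[nm]], units = unname(schema[[nm]]))),
      provenance = report$provenance)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null", digits = NA)
  } else {
    df <- data.frame(name = names(schema),
                     value = vapply(names(schema), function(nm) {
                       v <- vals[[nm]]
                       if (is.null(v)) NA_real_ else as.numeric(v)
                     }, numeric(1)),
                     units = unname(schema))
    write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read back a JSON histomorphometry report
#' @param path path written by [write_report()] with `format = "json"`.
#' @return a `histomorphometry_report`.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  vals <- list()
  for (mm in doc$measurements) vals[[mm$name]] <- mm$value
  build_report(values = vals, provenance = doc$provenance)
}
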