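# Phantom generator: synthetic bone sections with exact, closed-form ground
# truth. Phantoms stand in for scanned cryosections and provide the oracle
# for every downstream stage (stitching, registration, segmentation, ROI,
# projection, metrics).
#
# Geometry is deliberately restricted to axis-aligned stripes, annuli and
# rectangular shells so that truth quantities are closed-form. Mineralization
# label bands and cell blobs are only attached to the long faces of
# horizontal stripes; curved/shell primitives contribute unlabeled surface
# and are used for the cortex-repair and ROI scenarios.

#' Phantom specification
#'
#' Describes a synthetic two-label bone section. All physical quantities are
#' micrometers; they are converted to whole pixels at `pixel_size_um`.
#'
#' Trabecular primitives (list entries of `trabeculae`):
#' \describe{
#'   \item{stripe}{`list(type = "stripe", orientation = "horizontal" |
#'     "vertical", center_um, extent_um = c(lo, hi), width_um,
#'     labeled = TRUE/FALSE)`. Labels and cell sites attach only to
#'     horizontal labeled stripes.}
#'   \item{annulus}{`list(type = "annulus", cx_um, cy_um, r_outer_um,
#'     r_inner_um, gaps = list(list(theta_deg=, gap_um=)))` — a cortical ring,
#'     optionally with cut gaps (broken-cortex scenario).}
#'   \item{rect_shell}{`list(type = "rect_shell", x0_um, y0_um, x1_um, y1_um,
#'     thickness_um, gaps = list(list(side = "top|bottom|left|right",
#'     frac=, gap_um=)))` — a rectangular cortical shell.}
#' }
#'
#' Cell sites (`trap_sites`, `ap_sites`) are lists of
#' `list(stripe =, face = "top"|"bottom", frac =, on_label2 = FALSE,
#' off_surface = FALSE, dist_um = 0)`: a disk of diameter `cell_diameter_um`
#' anchored on (or `dist_um` off) the given stripe face. `on_label2` places
#' it over the second-label-covered part of the face, otherwise it is placed
#' beyond both label spans (unlabeled surface).
#'
#' @param image_shape integer (rows, cols) in pixels.
#' @param pixel_size_um micrometers per pixel.
#' @param trabeculae list of geometry primitives (see Details).
#' @param label1_offset_um,label2_offset_um distance of each label band's
#'   leading edge from the bone surface (depth into bone), um >= 0. The first
#'   injected label lies deeper, so normally `label1_offset_um >
#'   label2_offset_um`.
#' @param label_band_width_um width of each label band, um > 0.
#' @param labeled_fraction_l1,labeled_fraction_l2 fraction of each labeled
#'   face carrying the band, in [0, 1], covered from the left face end.
#' @param trap_sites,ap_sites cell site lists (see Details).
#' @param cell_diameter_um diameter of cell blobs, um.
#' @param bead_centers_um list/matrix of (x, y) fiducial bead centers, um.
#' @param bead_diameter_um bead diameter (6 um calibrated beads).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; truncated at zero).
#' @param intensity named list of channel intensities
#'   (background, marrow, bone, label, cell, bead).
#' @param proximity_um cell-to-surface proximity used when deriving truth
#'   cellular surface fractions (default 25.6 um).
#' @param seed integer RNG seed; a fixed seed makes the phantom bit-identical.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(image_shape,
                         pixel_size_um = 2,
                         trabeculae = list(),
                         label1_offset_um = 15,
                         label2_offset_um = 5,
                         label_band_width_um = 6,
                         labeled_fraction_l1 = 0.6,
                         labeled_fraction_l2 = 0.8,
                         trap_sites = list(),
                         ap_sites = list(),
                         cell_diameter_um = 14,
                         bead_centers_um = list(),
                         bead_diameter_um = 6,
                         noise_sd = 5,
                         intensity = list(),
                         proximity_um = 25.6,
                         seed = 1L) {
  check_pixel_size(pixel_size_um)
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 16L))
    stop("image_shape must be (rows, cols), each >= 16")
  if (label1_offset_um < 0 || label2_offset_um < 0)
    stop("label offsets must be >= 0")
  if (label_band_width_um <= 0) stop("label_band_width_um must be > 0")
  if (labeled_fraction_l1 < 0 || labeled_fraction_l1 > 1 ||
      labeled_fraction_l2 < 0 || labeled_fraction_l2 > 1)
    stop("labeled fractions must lie in [0, 1]")
  intensity <- modifyList(list(background = 30, marrow = 110, bone = 600,
                               label = 700, cell = 700, bead = 900), intensity)
  spec <- list(image_shape = image_shape, pixel_size_um = pixel_size_um,
               trabeculae = trabeculae,
               label1_offset_um = label1_offset_um,
               label2_offset_um = label2_offset_um,
               label_band_width_um = label_band_width_um,
               labeled_fraction_l1 = labeled_fraction_l1,
               labeled_fraction_l2 = labeled_fraction_l2,
               trap_sites = trap_sites, ap_sites = ap_sites,
               cell_diameter_um = cell_diameter_um,
               bead_centers_um = bead_centers_um,
               bead_diameter_um = bead_diameter_um,
               noise_sd = noise_sd, intensity = intensity,
               proximity_um = proximity_um, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_geometry(spec)
  spec
}

validate_phantom_geometry <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ps <- spec$pixel_size_um
  for (i in seq_along(spec$trabeculae)) {
    p <- spec$trabeculae[[i]]
    bad <- function(msg) stop(sprintf("primitive %d (%s): %s", i, p$type, msg))
    if (p$type == "stripe") {
      w <- um_to_px(p$width_um, ps)
      lo <- um_to_px(p$extent_um[1], ps); hi <- um_to_px(p$extent_um[2], ps)
      ctr <- um_to_px(p$center_um, ps)
      if (lo < 0 || hi - 1 > (if (p$orientation == "horizontal") nc else nr) - 1)
        bad("extent outside image")
      half <- w %/% 2
      if (ctr - half < 0 ||
          ctr - half + w - 1 > (if (p$orientation == "horizontal") nr else nc) - 1)
        bad("width outside image")
      if (isTRUE(p$labeled)) {
        if (p$orientation != "horizontal")
          bad("labels are only supported on horizontal stripes")
        depth <- um_to_px(max(spec$label1_offset_um, spec$label2_offset_um) +
                          spec$label_band_width_um, ps)
        if (depth > w %/% 2)
          bad("label bands deeper than half the stripe width")
      }
    } else if (p$type == "annulus") {
      if (um_to_px(p$cx_um - p$r_outer_um, ps) < 0 ||
          um_to_px(p$cy_um - p$r_outer_um, ps) < 0 ||
          um_to_px(p$cx_um + p$r_outer_um, ps) > nc - 1 ||
          um_to_px(p$cy_um + p$r_outer_um, ps) > nr - 1)
        bad("outer radius outside image")
      if (p$r_inner_um < 0 || p$r_inner_um >= p$r_outer_um)
        bad("need 0 <= r_inner < r_outer")
    } else if (p$type == "rect_shell") {
      if (um_to_px(p$x0_um, ps) < 0 || um_to_px(p$y0_um, ps) < 0 ||
          um_to_px(p$x1_um, ps) > nc - 1 || um_to_px(p$y1_um, ps) > nr - 1)
        bad("outer rectangle outside image")
      if (p$thickness_um <= 0) bad("thickness must be > 0")
    } else bad("unknown primitive type")
  }
  invisible(spec)
}

# --- rendering helpers -----------------------------------------------------

render_primitive <- function(mask, p, ps) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (p$type == "stripe") {
    w <- um_to_px(p$width_um, ps); half <- w %/% 2
    ctr <- um_to_px(p$center_um, ps)
    lo <- um_to_px(p$extent_um[1], ps); hi <- um_to_px(p$extent_um[2], ps)
    if (p$orientation == "horizontal") {
      mask[(ctr - half):(ctr - half + w - 1) + 1, lo:(hi) + 1] <- TRUE
    } else {
      mask[lo:(hi) + 1, (ctr - half):(ctr - half + w - 1) + 1] <- TRUE
    }
  } else if (p$type == "annulus") {
    cx <- p$cx_um / ps; cy <- p$cy_um / ps
    ro <- p$r_outer_um / ps; ri <- p$r_inner_um / ps
    rows <- matrix(0:(nr - 1), nr, nc)
    cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    d2 <- (rows - cy)^2 + (cols - cx)^2
    ring <- d2 <= ro^2 & d2 >= ri^2
    for (g in p$gaps %||% list()) {
      th <- deg2rad(g$theta_deg)
      gx <- cx + cos(th) * (ro + ri) / 2
      gy <- cy + sin(th) * (ro + ri) / 2
      gr <- (g$gap_um / ps) / 2
      ring <- ring & ((rows - gy)^2 + (cols - gx)^2 > gr^2)
    }
    mask <- mask | ring
  } else if (p$type == "rect_shell") {
    x0 <- um_to_px(p$x0_um, ps); y0 <- um_to_px(p$y0_um, ps)
    x1 <- um_to_px(p$x1_um, ps); y1 <- um_to_px(p$y1_um, ps)
    t <- um_to_px(p$thickness_um, ps)
    shell <- matrix(FALSE, nr, nc)
    shell[y0:y1 + 1, x0:x1 + 1] <- TRUE
    shell[(y0 + t):(y1 - t) + 1, (x0 + t):(x1 - t) + 1] <- FALSE
    for (g in p$gaps %||% list()) {
      gpx <- um_to_px(g$gap_um, ps)
      if (g$side %in% c("top", "bottom")) {
        gc <- x0 + round(g$frac * (x1 - x0))
        rows <- if (g$side == "top") y0:(y0 + t) else (y1 - t):y1
        shell[rows + 1, max(0, gc - gpx %/% 2):min(nc - 1, gc + gpx %/% 2) + 1] <- FALSE
      } else {
        gr <- y0 + round(g$frac * (y1 - y0))
        cols <- if (g$side == "left") x0:(x0 + t) else (x1 - t):x1
        shell[max(0, gr - gpx %/% 2):min(nr - 1, gr + gpx %/% 2) + 1, cols + 1] <- FALSE
      }
    }
    mask <- mask | shell
  }
  mask
}

# Per labeled horizontal stripe face geometry, all in 0-based pixels.
stripe_faces <- function(spec) {
  ps <- spec$pixel_size_um
  out <- NULL
  for (i in seq_along(spec$trabeculae)) {
    p <- spec$trabeculae[[i]]
    if (p$type != "stripe" || p$orientation != "horizontal") next
    w <- um_to_px(p$width_um, ps); half <- w %/% 2
    ctr <- um_to_px(p$center_um, ps)
    lo <- um_to_px(p$extent_um[1], ps); hi <- um_to_px(p$extent_um[2], ps)
    r0 <- ctr - half; r1 <- r0 + w - 1
    for (face in c("top", "bottom")) {
      out <- rbind(out, data.frame(
        stripe = i, face = face,
        row = if (face == "top") r0 else r1,
        col0 = lo, col1 = hi, labeled = isTRUE(p$labeled),
        width_px = w, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Generate a trabecular phantom
#'
#' Renders the mineral, label1, label2, TRAP, AP and DAPI channels described
#' by a [phantom_spec()] and returns them as a [build_stack()] channel stack
#' together with exhaustive analytic ground truth. Truth surface fractions
#' are computed from the spec arithmetic (face lengths, covered spans),
#' never by re-measuring the rendered raster.
#'
#' @param spec a [phantom_spec()].
#' @return `list(stack = channel_stack, truth = phantom_truth)`.
#' @export
make_trabecular_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ps <- spec$pixel_size_um
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  inten <- spec$intensity

  bone <- matrix(FALSE, nr, nc)
  for (p in spec$trabeculae) bone <- render_primitive(bone, p, ps)

  faces <- stripe_faces(spec)
  o1 <- um_to_px(spec$label1_offset_um, ps)
  o2 <- um_to_px(spec$label2_offset_um, ps)
  bw <- max(1L, um_to_px(spec$label_band_width_um, ps))

  # label bands are inset a few pixels from the stripe ends: subsurface
  # mineralization lines do not outcrop on the end faces. Truth spans use
  # the spec arithmetic (round(fraction x face length)); rendered spans are
  # clamped to the inset face with a warning when a fraction near 1 would
  # reach the ends.
  end_margin <- 3L
  lab1 <- matrix(FALSE, nr, nc); lab2 <- matrix(FALSE, nr, nc)
  if (!is.null(faces)) {
    for (j in seq_len(nrow(faces))) {
      f <- faces[j, ]
      if (!f$labeled) next
      L <- f$col1 - f$col0 + 1
      n1 <- round(spec$labeled_fraction_l1 * L)
      n2 <- round(spec$labeled_fraction_l2 * L)
      put_band <- function(m, o, ncov) {
        if (ncov < 1) return(m)
        c0 <- f$col0 + end_margin
        c1 <- min(c0 + ncov - 1, f$col1 - end_margin)
        if (c1 - c0 + 1 < ncov)
          warning("label band clamped at the stripe end margin; rendered coverage below the specified fraction")
        rows <- if (f$face == "top") (f$row + o):(f$row + o + bw - 1)
                else (f$row - o - bw + 1):(f$row - o)
        m[rows + 1, c0:c1 + 1] <- TRUE
        m
      }
      lab1 <- put_band(lab1, o1, n1)
      lab2 <- put_band(lab2, o2, n2)
    }
  }

  # section box (marrow background region for the cell channels): bounding
  # box of all bone geometry, expanded by 20 um
  mar <- um_to_px(20, ps)
  if (any(bone)) {
    wb <- which(bone, arr.ind = TRUE)
    box <- c(r0 = max(1, min(wb[, 1]) - mar), r1 = min(nr, max(wb[, 1]) + mar),
             c0 = max(1, min(wb[, 2]) - mar), c1 = min(nc, max(wb[, 2]) + mar))
  } else box <- c(r0 = 1, r1 = nr, c0 = 1, c1 = nc)

  cell_r <- max(1L, um_to_px(spec$cell_diameter_um / 2, ps))
  place_sites <- function(sites) {
    msk <- matrix(FALSE, nr, nc)
    info <- NULL
    for (s in sites) {
      f <- faces[faces$stripe == s$stripe & faces$face == s$face, ]
      if (nrow(f) != 1) stop("cell site references a missing stripe face")
      L <- f$col1 - f$col0 + 1
      n2 <- round(spec$labeled_fraction_l2 * L)
      nmax <- max(round(spec$labeled_fraction_l1 * L), n2)
      frac <- s$frac %||% 0.5
      if (isTRUE(s$on_label2)) {
        if (n2 < 2 * cell_r + 1) stop("label2 span too short for an on-label2 site")
        xc <- f$col0 + 3L + cell_r + round(frac * (n2 - 1 - 2 * cell_r))
      } else {
        lo <- f$col0 + 3L + nmax + cell_r
        hi <- f$col1 - 3L - cell_r
        if (hi < lo) stop("unlabeled face span too short for a cell site")
        xc <- lo + round(frac * (hi - lo))
      }
      dist_px <- if (isTRUE(s$off_surface)) um_to_px(s$dist_um %||% 40, ps) else 0L
      yc <- if (s$face == "top") f$row - dist_px - cell_r
            else f$row + dist_px + cell_r
      msk <- draw_disk(msk, xc, yc, cell_r, TRUE)
      info <- rbind(info, data.frame(
        stripe = s$stripe, face = s$face, x = xc, y = yc,
        on_label2 = isTRUE(s$on_label2), off_surface = isTRUE(s$off_surface),
        dist_um = dist_px * ps, span_px = 2 * cell_r + 1))
    }
    list(mask = msk, info = info)
  }
  trap <- place_sites(spec$trap_sites)
  ap <- place_sites(spec$ap_sites)

  # channels
  marrow_bg <- matrix(inten$background, nr, nc)
  marrow_bg[box["r0"]:box["r1"], box["c0"]:box["c1"]] <- inten$marrow

  ch_mineral <- matrix(inten$background, nr, nc); ch_mineral[bone] <- inten$bone
  ch_l1 <- matrix(inten$background, nr, nc); ch_l1[lab1] <- inten$label
  ch_l2 <- matrix(inten$background, nr, nc); ch_l2[lab2] <- inten$label
  ch_trap <- marrow_bg; ch_trap[trap$mask] <- inten$cell
  ch_ap <- marrow_bg; ch_ap[ap$mask] <- inten$cell
  ch_dapi <- matrix(inten$background, nr, nc)

  # beads are visible in the label channels of the reference scan and in the
  # TRAP/AP channels of the stain scans
  bead_r <- max(1, spec$bead_diameter_um / 2 / ps)
  beads <- spec$bead_centers_um
  if (length(beads)) {
    bm <- do.call(rbind, lapply(beads, function(b) b / ps))
    for (i in seq_len(nrow(bm))) {
      for (nm in c("ch_l1", "ch_l2", "ch_trap", "ch_ap")) {
        assign(nm, draw_disk(get(nm), bm[i, 1], bm[i, 2], bead_r, inten$bead))
      }
    }
  }

  chans <- with_seed(spec$seed, {
    # scatter a few DAPI nuclei in the marrow for channel completeness
    ndots <- max(5L, as.integer((box["r1"] - box["r0"]) *
                                (box["c1"] - box["c0"]) / 8000))
    dx <- runif(ndots, box["c0"] - 1, box["c1"] - 1)
    dy <- runif(ndots, box["r0"] - 1, box["r1"] - 1)
    for (i in seq_len(ndots))
      ch_dapi <- draw_disk(ch_dapi, dx[i], dy[i], cell_r / 2, inten$cell)
    lst <- list(mineral = ch_mineral, label1 = ch_l1, label2 = ch_l2,
                trap = ch_trap, ap = ch_ap, dapi = ch_dapi)
    if (spec$noise_sd > 0) {
      lst <- lapply(lst, function(m)
        pmax(m + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc), 0))
    }
    lst
  })

  stack <- build_stack(lapply(chans, raster_image, pixel_size_um = ps),
                       site = "femur")

  truth <- phantom_truth(spec, bone, faces, trap$info, ap$info, o1, o2)
  truth$label1_mask <- binary_mask(lab1, ps, "label1")
  truth$label2_mask <- binary_mask(lab2, ps, "label2")
  truth$trap_mask <- binary_mask(trap$mask, ps, "trap")
  truth$ap_mask <- binary_mask(ap$mask, ps, "ap")
  list(stack = stack, truth = truth)
}

# Analytic truth: every fraction from the spec arithmetic. Surface fractions
# refer to the trabecular (stripe) surface — cortical shells/annuli always
# lie outside the analysis ROI — and use the closed-form digital perimeter
# of each stripe (2L + 2W - 4). Phantoms without stripes provide only the
# masks/geometry.
phantom_truth <- function(spec, bone, faces, trap_info, ap_info, o1, o2) {
  ps <- spec$pixel_size_um
  if (!is.null(faces)) {
    L <- faces$col1 - faces$col0 + 1
    faces$l1_px <- ifelse(faces$labeled, round(spec$labeled_fraction_l1 * L), 0)
    faces$l2_px <- ifelse(faces$labeled, round(spec$labeled_fraction_l2 * L), 0)
  }
  tr <- list(
    bone_mask = binary_mask(bone, ps, "mineral"),
    bone_area_px = sum(bone),
    pixel_size_um = ps,
    true_interlabel_um = (o1 - o2) * ps,
    faces = faces,
    trap_sites = trap_info,
    ap_sites = ap_info,
    true_transform = NULL,
    tile_offsets = NULL
  )
  stripes <- Filter(function(p) p$type == "stripe", spec$trabeculae)
  if (length(stripes)) {
    per <- 0; n_l1 <- 0; n_l2 <- 0; n_d <- 0
    for (p in stripes) {
      w <- um_to_px(p$width_um, ps)
      lo <- um_to_px(p$extent_um[1], ps); hi <- um_to_px(p$extent_um[2], ps)
      L <- hi - lo + 1
      per <- per + 2 * L + 2 * w - 4
      if (p$orientation == "horizontal" && isTRUE(p$labeled)) {
        c1 <- round(spec$labeled_fraction_l1 * L)
        c2 <- round(spec$labeled_fraction_l2 * L)
        n_l1 <- n_l1 + 2 * c1
        n_l2 <- n_l2 + 2 * c2
        n_d <- n_d + 2 * min(c1, c2)
      }
    }
    sl1 <- n_l1 - n_d; sl2 <- n_l2 - n_d
    sls <- sl1 + sl2
    f <- function(n) 100 * n / per
    cell_frac <- function(info, on_l2) {
      if (is.null(info)) return(0)
      sel <- info$on_label2 == on_l2 & info$dist_um <= spec$proximity_um
      f(sum(info$span_px[sel]))
    }
    tr <- c(tr, list(
      surface_px = per,
      l1_bs = f(n_l1), l2_bs = f(n_l2),
      l1_only_bs = f(sl1), l2_only_bs = f(sl2),
      sls_bs = f(sls), dls_bs = f(n_d),
      ls_bs = f(sls + n_d), ms_bs = f(n_d) + f(sls) / 2,
      trap_l2_bs = cell_frac(trap_info, TRUE),
      trap_only_bs = cell_frac(trap_info, FALSE),
      ap_l2_bs = cell_frac(ap_info, TRUE),
      ap_only_bs = cell_frac(ap_info, FALSE)
    ))
    tr$trap_bs <- tr$trap_l2_bs + tr$trap_only_bs
    tr$ap_bs <- tr$ap_l2_bs + tr$ap_only_bs
  } else {
    tr$surface_px <- NA_real_
  }
  class(tr) <- "phantom_truth"
  tr
}

#' Split an image into overlapping tiles
#'
#' Emulates microscope tile scanning: adjacent tiles share a 10-15 percent
#' overlap. Placing the tiles back at the returned truth offsets reproduces
#' the input bit-exactly.
#'
#' @param image a [raster_image()] (or matrix).
#' @param tile_shape integer (rows, cols) of each tile.
#' @param overlap_fraction nominal overlap fraction; values outside
#'   [0.05, 0.5] are rejected.
#' @return `list(grid = tile_grid, offsets = matrix)` where `offsets` has one
#'   row per tile: grid_row, grid_col, row0, col0 (0-based placements).
#' @export
split_into_tiles <- function(image, tile_shape, overlap_fraction) {
  if (overlap_fraction < 0.05 || overlap_fraction > 0.5)
    stop("overlap_fraction must lie in [0.05, 0.5]")
  tile_shape <- as.integer(tile_shape)
  nr <- nrow(image); nc <- ncol(image)
  if (tile_shape[1] >= nr || tile_shape[2] >= nc)
    stop("tile_shape must be smaller than the image")
  pos1 <- function(n, t) {
    stride <- t - as.integer(round(t * overlap_fraction))
    k <- max(1L, as.integer(ceiling((n - t) / stride)) + 1L)
    p <- unique(as.integer(round(seq(0, n - t, length.out = k))))
    if (length(p) > 1) {
      ach <- (t - min(diff(p))) / t
      if (abs(ach - overlap_fraction) > 0.5 * overlap_fraction)
        warning(sprintf("achieved overlap %.3f deviates from requested %.3f (image size does not divide evenly)",
                        ach, overlap_fraction))
    }
    p
  }
  rows <- pos1(nr, tile_shape[1]); cols <- pos1(nc, tile_shape[2])
  tiles <- vector("list", length(rows) * length(cols))
  offsets <- NULL
  k <- 0L
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    k <- k + 1L
    tiles[[k]] <- as_plain(image)[rows[i] + seq_len(tile_shape[1]),
                                  cols[j] + seq_len(tile_shape[2]), drop = FALSE]
    offsets <- rbind(offsets, c(grid_row = i, grid_col = j,
                                row0 = rows[i], col0 = cols[j]))
  }
  grid <- tile_grid(tiles, grid_shape = c(length(rows), length(cols)),
                    tile_shape = tile_shape,
                    nominal_overlap = overlap_fraction,
                    pixel_size_um = attr(image, "pixel_size_um") %||% 1)
  list(grid = grid, offsets = offsets)
}

#' Apply a known similarity transform to selected channels
#'
#' Produces a mis-registered "stain scan" from a reference stack: each listed
#' channel is resampled so that the output pixel at moving coordinate p takes
#' the reference value at `T(p)` (with `T` mapping moving to reference
#' coordinates, see [similarity_transform()]). The identity transform
#' returns the channels bit-exactly.
#'
#' @param stack a channel stack.
#' @param transform a [similarity_transform()]; |rotation| <= 30 degrees and
#'   scale in [0.9, 1.1] (plausible stage/tape effects).
#' @param channels character vector of channel roles to transform.
#' @return the stack with the listed channels resampled; the applied
#'   transform is recorded as attribute `true_transform`.
#' @export
apply_similarity <- function(stack, transform,
                             channels = intersect(c("trap", "ap"),
                                                  names(stack$channels))) {
  stopifnot(inherits(transform, "similarity_transform"))
  if (transform$scale <= 0) stop("scale must be > 0")
  if (abs(transform$rotation_deg) > 30 ||
      transform$scale < 0.9 || transform$scale > 1.1)
    stop("transform outside plausible bounds (|rot| <= 30 deg, scale in [0.9, 1.1])")
  for (role in channels) {
    ch <- stack$channels[[role]]
    if (is.null(ch)) stop(sprintf("channel '%s' absent", role))
    nr <- nrow(ch); nc <- ncol(ch)
    grid_x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    grid_y <- matrix(0:(nr - 1), nr, nc)
    src <- tf_apply(transform, cbind(as.vector(grid_x), as.vector(grid_y)))
    vals <- bilinear_sample(as_plain(ch), src[, 1], src[, 2], fill = 0)
    out <- matrix(vals, nr, nc)
    stack$channels[[role]] <- raster_image(out, pixel_size(ch))
  }
  attr(stack, "true_transform") <- transform
  stack
}

#' Add a linear shading field
#'
#' Emulates inhomogeneous illumination: `output = input + gx * col +
#' gy * row + offset`, clipped to `[0, max_intensity]`. Clipping at the top
#' of the range is reported with a warning.
#'
#' @param image raster image or matrix.
#' @param ramp numeric (gx, gy), intensity change per pixel along columns and
#'   rows.
#' @param offset constant intensity offset.
#' @param max_intensity upper clip bound (default 65535).
#' @return shaded image of the same class.
#' @export
add_shading <- function(image, ramp, offset = 0, max_intensity = 65535) {
  nr <- nrow(image); nc <- ncol(image)
  field <- outer(rep(1, nr), (0:(nc - 1)) * ramp[1]) +
    outer((0:(nr - 1)) * ramp[2], rep(1, nc)) + offset
  out <- as_plain(image) + field
  nclip <- sum(out > max_intensity)
  if (nclip > 0)
    warning(sprintf("%d pixels clipped to max intensity %g", nclip, max_intensity))
  out <- pmin(pmax(out, 0), max_intensity)
  if (inherits(image, "raster_image")) raster_image(out, pixel_size(image))
  else out
}
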