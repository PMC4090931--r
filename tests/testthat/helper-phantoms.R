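# Shared phantom builders for the test suite. All fixtures are generated in
# code; seeds are fixed per call site.

# two labeled horizontal stripes, closed-form truth for every surface ratio
stripe_phantom_spec <- function(pixel_size_um = 2.5, noise_sd = 5, seed = 1,
                                f1 = 0.6, f2 = 0.8,
                                o1 = 15, o2 = 5,
                                trap_sites = list(), ap_sites = list(),
                                beads = list()) {
  phantom_spec(
    image_shape = c(300, 400), pixel_size_um = pixel_size_um,
    trabeculae = list(
      list(type = "stripe", orientation = "horizontal", center_um = 250,
           extent_um = c(100, 880), width_um = 60, labeled = TRUE),
      list(type = "stripe", orientation = "horizontal", center_um = 500,
           extent_um = c(100, 880), width_um = 60, labeled = TRUE)),
    label1_offset_um = o1, label2_offset_um = o2, label_band_width_um = 6,
    labeled_fraction_l1 = f1, labeled_fraction_l2 = f2,
    trap_sites = trap_sites, ap_sites = ap_sites,
    bead_centers_um = beads, noise_sd = noise_sd, seed = seed)
}

# femur-like phantom: rectangular cortical shell with labeled trabecular
# stripes, cell sites and corner beads; growth plate at row 170
femur_phantom_spec <- function(pixel_size_um = 2.5, noise_sd = 5, seed = 1,
                               gaps = list()) {
  phantom_spec(
    image_shape = c(1150, 950), pixel_size_um = pixel_size_um,
    trabeculae = c(
      list(list(type = "rect_shell", x0_um = 100, y0_um = 100,
                x1_um = 2270, y1_um = 2770, thickness_um = 100, gaps = gaps)),
      lapply(c(1300, 1600, 1900, 2200), function(y)
        list(type = "stripe", orientation = "horizontal", center_um = y,
             extent_um = c(550, 1800), width_um = 60, labeled = TRUE))),
    label1_offset_um = 15, label2_offset_um = 5, label_band_width_um = 6,
    labeled_fraction_l1 = 0.6, labeled_fraction_l2 = 0.8,
    trap_sites = list(
      list(stripe = 2, face = "top", frac = 0.3, on_label2 = TRUE),
      list(stripe = 3, face = "bottom", frac = 0.5, on_label2 = FALSE),
      list(stripe = 4, face = "top", frac = 0.7, on_label2 = FALSE,
           off_surface = TRUE, dist_um = 40)),
    ap_sites = list(
      list(stripe = 2, face = "bottom", frac = 0.4, on_label2 = TRUE),
      list(stripe = 3, face = "top", frac = 0.6, on_label2 = FALSE)),
    bead_centers_um = list(c(320, 320), c(2050, 330), c(2060, 2580),
                           c(310, 2570)),
    noise_sd = noise_sd, seed = seed)
}

# flat-surface fixture: bone slab below row `bone_row0` (0-based), pixel
# size 1 um
flat_fixture <- function(nr = 200, nc = 100, bone_row0 = 100) {
  bone <- matrix(FALSE, nr, nc)
  bone[(bone_row0 + 1):min(nr, bone_row0 + 40), ] <- TRUE
  binary_mask(bone, 1)
}

# brute-force spatial-domain cross-correlation peak over all cyclic shifts
# (oracle for the FFT correlation path); the reported shift s satisfies
# b(p) = a(p + s), matching kth_law_correlate's convention
brute_force_ncc_peak <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  best <- c(NA, NA); best_v <- -Inf
  av <- a - mean(a)
  for (dy in 0:(nr - 1)) for (dx in 0:(nc - 1)) {
    bs <- b[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
    v <- sum(av * (bs - mean(bs)))
    if (v > best_v) { best_v <- v; best <- c(dy, dx) }
  }
  wrap <- function(v, n) if (v > n / 2) v - n else v
  c(dy = wrap(best[1], nr), dx = wrap(best[2], nc))
}

# naive exhaustive Otsu oracle: direct between-class variance enumeration
# over the same 256-bin histogram definition
naive_otsu <- function(values, nbins = 256L) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  bin <- pmin(pmax(findInterval(values, breaks, all.inside = TRUE), 1), nbins)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  best_k <- NA; best_v <- -Inf
  for (k in 1:(nbins - 1)) {
    lo <- bin <= k
    n0 <- sum(lo); n1 <- sum(!lo)
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / length(values)
    mu0 <- mean(mids[bin[lo]]); mu1 <- mean(mids[bin[!lo]])
    v <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_k <- k }
  }
  breaks[best_k + 1]
}

# per-pixel ray-marching projection oracle: march every signal pixel
# independently along direction d until it reaches the target set
ray_march_oracle <- function(signal, bone, d, target = c("bone", "contour"),
                             tmax = 200) {
  target <- match.arg(target)
  bm <- as.matrix(bone) > 0
  tg <- if (target == "bone") bm else {
    bnd <- bonemorph:::boundary_pixels(bm)
    bnd | !bm
  }
  w <- which(as.matrix(signal) > 0, arr.ind = TRUE)
  travels <- rep(NA_real_, nrow(w))
  for (i in seq_len(nrow(w))) {
    for (t in 0:tmax) {
      r <- w[i, 1] + round(t * d[2]); c <- w[i, 2] + round(t * d[1])
      if (r < 1 || r > nrow(bm) || c < 1 || c > ncol(bm)) break
      if (tg[r, c]) { travels[i] <- t; break }
    }
  }
  travels
}

mask_iou <- function(a, b) {
  a <- as.matrix(a) > 0; b <- as.matrix(b) > 0
  sum(a & b) / sum(a | b)
}
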