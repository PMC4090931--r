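# Surface normals, signal projection, inter-label thickness and surface
# classification.

test_that("flat-face normals are exact and circle normals near-radial", {
  m <- matrix(FALSE, 80, 80); m[30:60, 20:60] <- TRUE
  surf <- surface_normals(binary_mask(m, 1))
  # away from the corners (outside the smoothing kernel's reach) the
  # flat-face normal is exact
  top <- surf$pixels[surf$pixels$row0 == 29 & surf$pixels$col0 %in% 30:49, ]
  expect_true(all(abs(top$nx) < 1e-9))
  expect_equal(top$ny, rep(-1, nrow(top)), tolerance = 1e-12)
  # circle of radius 50
  circ <- bonemorph:::draw_disk(matrix(FALSE, 140, 140), 69, 69, 50, TRUE)
  sc <- surface_normals(binary_mask(circ, 1))
  rad_x <- sc$pixels$col0 - 69; rad_y <- sc$pixels$row0 - 69
  rn <- sqrt(rad_x^2 + rad_y^2)
  cosang <- (sc$pixels$nx * rad_x + sc$pixels$ny * rad_y) / rn
  expect_gt(min(cosang), cos(bonemorph:::deg2rad(3)))
  expect_error(surface_normals(binary_mask(matrix(FALSE, 10, 10), 1)), "empty")
})

test_that("chains are closed 8-connected cycles", {
  m <- matrix(FALSE, 60, 60); m[15:45, 10:50] <- TRUE
  surf <- surface_normals(binary_mask(m, 1))
  expect_equal(length(surf$chains), 1L)
  ch <- surf$chains[[1]]
  steps <- abs(diff(rbind(ch, ch[1, ])))
  expect_true(all(steps <= 1))                 # 8-connected, closed
  expect_equal(nrow(ch), 2 * 31 + 2 * 41 - 4)  # full rectangle boundary
})

test_that("leading edge and midpoint equal the ray-marching oracle on a flat face", {
  bone <- flat_fixture()
  sig <- matrix(FALSE, 200, 100)
  sig[(87:90) + 1, 21:61] <- TRUE     # thickness 4, leading edge 10 px above
  surf <- surface_normals(bone)
  pr <- project_signal(binary_mask(sig, 1), bone, surf, max_travel_um = 50)
  expect_equal(pr$components$leading_px, 10)
  expect_equal(pr$components$midpoint_px, 12)  # 10 + 4/2
  oracle <- ray_march_oracle(sig, bone, d = c(0, 1), target = "bone")
  expect_equal(pr$components$leading_px, min(oracle))
  expect_equal(pr$components$midpoint_px,
               min(oracle) + (max(oracle) - min(oracle) + 1) / 2)
  # hit pixels cover exactly the contact span
  hit_cols <- sort(surf$pixels$col0[pr$hits$surf_idx])
  expect_equal(hit_cols, 20:60)
  # a band already touching the surface travels zero
  touching <- matrix(FALSE, 200, 100); touching[(97:100) + 1, 21:61] <- TRUE
  p0 <- project_signal(binary_mask(touching, 1), bone, surf, 50)
  expect_equal(p0$components$leading_px, 0)
})

test_that("projection matches the oracle on a circular surface", {
  circ <- bonemorph:::draw_disk(matrix(FALSE, 160, 160), 79, 79, 45, TRUE)
  bone <- binary_mask(circ, 1)
  surf <- surface_normals(bone)
  # small blob straight above the circle: radial direction is (0, 1)
  sig <- bonemorph:::draw_disk(matrix(FALSE, 160, 160), 79, 20, 4, TRUE)
  pr <- project_signal(binary_mask(sig, 1), bone, surf, max_travel_um = 50)
  oracle <- ray_march_oracle(sig, bone, d = c(0, 1), target = "bone")
  expect_equal(pr$components$leading_px, min(oracle, na.rm = TRUE))
  expect_false(pr$components$discarded)
})

test_that("inter-label thickness recovers constructed and phantom offsets", {
  bone <- flat_fixture()
  surf <- surface_normals(bone)
  mk <- function(depth0, depth1) {
    m <- matrix(FALSE, 200, 100); m[(100 + depth0):(100 + depth1) + 1, 21:61] <- TRUE
    binary_mask(m, 1)
  }
  p1 <- project_signal(mk(15, 18), bone, surf, 50)  # first label, deeper
  p2 <- project_signal(mk(5, 8), bone, surf, 50)
  ir <- interlabel_thickness(p1, p2, surf)
  expect_equal(ir$mean_um, 10)
  expect_equal(ir$n, 41)
  # coincident labels -> zero, not absent
  irc <- interlabel_thickness(p2, p2, surf)
  expect_equal(irc$mean_um, 0)
  expect_false(irc$absent)
  # disjoint labels -> absent result
  m2 <- matrix(FALSE, 200, 100); m2[(105:108) + 1, 70:90] <- TRUE
  p3 <- project_signal(binary_mask(m2, 1), bone, surf, 50)
  ir0 <- interlabel_thickness(p1, p3, surf)
  expect_true(ir0$absent)
  expect_null(ir0$mean_um)

  # phantom: mean within one pixel size of the analytic truth
  ph <- make_trabecular_phantom(stripe_phantom_spec(seed = 71))
  bone_m <- segment_channel(ph$stack, "mineral")
  surf_p <- surface_normals(bone_m)
  pl1 <- project_signal(segment_channel(ph$stack, "label1"), bone_m, surf_p, 50)
  pl2 <- project_signal(segment_channel(ph$stack, "label2"), bone_m, surf_p, 50)
  irp <- interlabel_thickness(pl1, pl2, surf_p)
  expect_lt(abs(irp$mean_um - ph$truth$true_interlabel_um), 2.5)
})

test_that("inter-label thickness is invariant under 90 degree rotation", {
  ph <- make_trabecular_phantom(stripe_phantom_spec(seed = 72, noise_sd = 0))
  measure <- function(stack) {
    bone <- segment_channel(stack, "mineral")
    surf <- surface_normals(bone)
    p1 <- project_signal(segment_channel(stack, "label1"), bone, surf, 50)
    p2 <- project_signal(segment_channel(stack, "label2"), bone, surf, 50)
    interlabel_thickness(p1, p2, surf)$mean_um
  }
  base <- measure(ph$stack)
  rot <- ph$stack
  rot$channels <- lapply(rot$channels, function(ch)
    raster_image(t(unclass(ch))[ncol(ch):1, ], pixel_size(ch)))
  expect_equal(measure(rot), base)
})

test_that("the proximity rule separates surface from marrow cells", {
  bone <- flat_fixture()
  surf <- surface_normals(bone)
  near <- bonemorph:::draw_disk(matrix(FALSE, 200, 100), 30, 95, 3, TRUE)
  far <- bonemorph:::draw_disk(matrix(FALSE, 200, 100), 70, 67, 3, TRUE)  # 30 px off
  ptrap <- project_signal(binary_mask(near | far, 1), bone, surf,
                          max_travel_um = 77)
  cls <- classify_surface(surf, list(trap = ptrap), proximity_um = 25.6)
  hit_cols <- cls$col0[cls$TRAP]
  expect_true(all(hit_cols %in% 26:34))  # only the near blob contributes
  expect_equal(sum(cls$TRAP), 7)
  # without signals everything is unlabeled
  cls0 <- classify_surface(surf, list(), proximity_um = 25.6)
  expect_true(all(cls0$unlabeled))
  expect_false(any(cls0$L1 | cls0$L2 | cls0$AP | cls0$TRAP))
})

test_that("exclusive classes partition the surface exactly", {
  ph <- make_trabecular_phantom(stripe_phantom_spec(
    seed = 73,
    trap_sites = list(list(stripe = 1, face = "top", frac = 0.2, on_label2 = TRUE)),
    ap_sites = list(list(stripe = 2, face = "bottom", frac = 0.5))))
  bone <- segment_channel(ph$stack, "mineral")
  surf <- surface_normals(bone)
  projections <- list(
    label1 = project_signal(segment_channel(ph$stack, "label1"), bone, surf, 50),
    label2 = project_signal(segment_channel(ph$stack, "label2"), bone, surf, 50),
    trap = project_signal(segment_channel(ph$stack, "trap"), bone, surf, 77),
    ap = project_signal(segment_channel(ph$stack, "ap"), bone, surf, 77))
  cls <- classify_surface(surf, projections)
  expect_equal(sum(cls$sL1) + sum(cls$sL2) + sum(cls$dL) + sum(cls$unlabeled),
               nrow(cls))
  expect_identical(cls$L2, cls$sL2 | cls$dL)
  expect_identical(cls$L1, cls$sL1 | cls$dL)
  # phantom cell-site truth: AP-on-L2 surface fraction within 2 surface px
  ap_l2_frac <- 100 * sum(cls$AP_L2) / ph$truth$surface_px
  expect_lt(abs(ap_l2_frac - ph$truth$ap_l2_bs),
            100 * 2 / ph$truth$surface_px + 1e-9)
})
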