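# Phantom generator: determinism, analytic truth self-consistency, tiling
# and the synthetic acquisition distortions.

test_that("phantom output is bit-identical for a fixed spec and seed", {
  spec <- stripe_phantom_spec(seed = 42)
  a <- make_trabecular_phantom(spec)
  b <- make_trabecular_phantom(spec)
  for (role in names(a$stack$channels))
    expect_identical(unclass(a$stack$channels[[role]]),
                     unclass(b$stack$channels[[role]]))
})

test_that("truth surface fractions obey the measurement identities exactly", {
  for (seed in 1:5) {
    f1 <- runif(1, 0.3, 0.7); f2 <- runif(1, 0.5, 0.9)
    tr <- make_trabecular_phantom(stripe_phantom_spec(seed = seed,
                                                      f1 = f1, f2 = f2))$truth
    expect_equal(tr$ls_bs, tr$sls_bs + tr$dls_bs)
    expect_equal(tr$ms_bs, tr$dls_bs + tr$sls_bs / 2)
    expect_equal(tr$l2_bs, tr$l2_only_bs + tr$dls_bs)
    expect_equal(tr$l1_bs, tr$l1_only_bs + tr$dls_bs)
    expect_lte(tr$ls_bs, 100)
    expect_gte(min(tr$sls_bs, tr$dls_bs), 0)
  }
})

test_that("truth inter-label thickness is the spec offset difference", {
  # at 1 um/px the stated offsets convert exactly
  spec <- phantom_spec(image_shape = c(120, 200), pixel_size_um = 1,
                       trabeculae = list(list(type = "stripe",
                                              orientation = "horizontal",
                                              center_um = 60,
                                              extent_um = c(20, 180),
                                              width_um = 50, labeled = TRUE)),
                       label1_offset_um = 15, label2_offset_um = 5,
                       noise_sd = 0)
  tr <- make_trabecular_phantom(spec)$truth
  expect_equal(tr$true_interlabel_um, 10)
})

test_that("full and empty label coverage give 100 and 0 percent truth", {
  full <- suppressWarnings(make_trabecular_phantom(
    stripe_phantom_spec(f1 = 0, f2 = 1, noise_sd = 0)))$truth
  # per-face truth: the label spans the entire face
  lens <- full$faces$col1 - full$faces$col0 + 1
  expect_equal(full$faces$l2_px, lens)
  none <- make_trabecular_phantom(stripe_phantom_spec(f1 = 0, f2 = 0,
                                                      noise_sd = 0))
  expect_equal(none$truth$ls_bs, 0)
  expect_equal(sum(none$truth$label1_mask), 0)
  expect_equal(sum(none$truth$label2_mask), 0)
})

test_that("out-of-bounds geometry is rejected naming the primitive", {
  expect_error(
    phantom_spec(image_shape = c(100, 100), pixel_size_um = 1,
                 trabeculae = list(
                   list(type = "stripe", orientation = "horizontal",
                        center_um = 50, extent_um = c(0, 99), width_um = 20),
                   list(type = "annulus", cx_um = 50, cy_um = 50,
                        r_outer_um = 90, r_inner_um = 40))),
    "primitive 2")
})

test_that("tile splitting is the exact inverse of placement at truth offsets", {
  set.seed(3)
  img <- raster_image(matrix(runif(380 * 380, 0, 1000), 380, 380), 2)
  sp <- split_into_tiles(img, c(200, 200), 0.10)
  canvas <- matrix(NA_real_, 380, 380)
  for (i in seq_len(nrow(sp$offsets))) {
    t <- sp$grid$tiles[[i]]
    rows <- sp$offsets[i, "row0"] + seq_len(nrow(t))
    cols <- sp$offsets[i, "col0"] + seq_len(ncol(t))
    canvas[rows, cols] <- t
  }
  expect_identical(canvas, unclass(img)[seq_len(380), seq_len(380)])
  # shared strip width: 10 percent of a 300 px tile is 30 px
  img2 <- raster_image(matrix(runif(570 * 570), 570, 570), 2)
  sp2 <- split_into_tiles(img2, c(300, 300), 0.10)
  expect_equal(sp2$grid$grid_shape, c(2L, 2L))
  expect_equal(diff(unique(sp2$offsets[, "col0"])), 270)  # 300 - 30 overlap
  expect_error(split_into_tiles(img, c(100, 100), 0.6), "overlap")
  expect_error(split_into_tiles(img, c(100, 100), 0.02), "overlap")
})

test_that("apply_similarity is exact for the identity and composes", {
  ph <- make_trabecular_phantom(stripe_phantom_spec(
    seed = 5, beads = list(c(60, 60), c(900, 80), c(880, 680), c(70, 700))))
  id <- similarity_transform()
  out <- apply_similarity(ph$stack, id)
  expect_identical(unclass(out$channels$trap), unclass(ph$stack$channels$trap))
  # two successive transforms equal their composition within resampling error
  t1 <- similarity_about_center(3, 0.99, 5, -3, center = c(200, 150))
  t2 <- similarity_about_center(-2, 1.01, -4, 6, center = c(200, 150))
  a <- apply_similarity(apply_similarity(ph$stack, t1), t2)
  b <- apply_similarity(ph$stack, bonemorph:::tf_compose(t1, t2))
  m1 <- unclass(a$channels$trap); m2 <- unclass(b$channels$trap)
  interior <- 30:270
  err <- mean(abs(m1[interior, interior] - m2[interior, interior]))
  expect_lt(err, 0.02 * diff(range(m2)))
  expect_error(apply_similarity(ph$stack, similarity_transform(scale = 0.5)),
               "bounds")
})

test_that("shading is an exact linear field with logged clipping", {
  z <- raster_image(matrix(0, 50, 80), 1)
  out <- add_shading(z, ramp = c(0.1, 0), offset = 0)
  expect_equal(unclass(out)[25, ], 0.1 * (0:79))
  expect_identical(unclass(add_shading(z, c(0, 0), 0)), unclass(z))
  big <- raster_image(matrix(60000, 10, 10), 1)
  expect_warning(out2 <- add_shading(big, c(1000, 0), 0), "clipped")
  expect_equal(max(out2), 65535)
})
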