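# Bead detection, matching and similarity estimation.

render_beads <- function(centers, nr = 300, nc = 300, radius = 3, value = 900,
                         bg = 30, ps = 1) {
  img <- matrix(bg, nr, nc)
  for (i in seq_len(nrow(centers)))
    img <- bonemorph:::draw_disk(img, centers[i, 1], centers[i, 2], radius, value)
  raster_image(img, ps)
}

test_that("beads at known centers are found within 0.5 px", {
  centers <- rbind(c(50, 60), c(250, 80), c(150, 240))
  bs <- detect_beads(render_beads(centers), expected_diameter_um = 6)
  expect_equal(nrow(bs), 3)
  got <- as.matrix(bs[order(bs$x), c("x", "y")])
  want <- centers[order(centers[, 1]), ]
  expect_lt(max(abs(got - want)), 0.5)
})

test_that("empty images and off-size blobs yield empty/filtered bead sets", {
  expect_equal(nrow(detect_beads(raster_image(matrix(30, 50, 50), 1), 6)), 0)
  big <- render_beads(rbind(c(150, 150)), radius = 10)   # 20 um blob, expect 6
  expect_equal(nrow(detect_beads(big, 6)), 0)
  mix <- render_beads(rbind(c(60, 60)), radius = 3)
  mix <- raster_image(bonemorph:::draw_disk(unclass(mix), 200, 200, 10, 900), 1)
  found <- detect_beads(mix, 6)
  expect_equal(nrow(found), 1)
  expect_lt(abs(found$x - 60), 0.5)
})

test_that("bead matching survives rotation and unequal cardinality", {
  set.seed(31)
  P <- cbind(x = runif(5, 50, 450), y = runif(5, 50, 450))
  as_beads <- function(m) structure(data.frame(x = m[, 1], y = m[, 2]),
                                    class = c("bead_set", "data.frame"))
  # identity pairing
  m0 <- match_beads(as_beads(P), as_beads(P))
  expect_equal(m0$ref, m0$mov)
  # rotation about the centroid with a permutation
  th <- bonemorph:::deg2rad(5)
  ctr <- colMeans(P)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Q <- sweep(sweep(P, 2, ctr) %*% t(R), 2, ctr, `+`)
  perm <- c(3, 1, 5, 2, 4)
  m1 <- match_beads(as_beads(P), as_beads(Q[perm, ]))
  expect_equal(nrow(m1), 5)
  expect_equal(perm[m1$mov], m1$ref)
  # 5 reference beads, 3 moving beads -> exactly 3 pairs
  m2 <- match_beads(as_beads(P), as_beads(Q[1:3, ]))
  expect_equal(nrow(m2), 3)
  expect_error(match_beads(as_beads(P[1, , drop = FALSE]), as_beads(Q)),
               "insufficient fiducials")
})

test_that("similarity fit is exact on clean pairs and matches grid search", {
  set.seed(32)
  n <- 10
  P <- cbind(runif(n, 50, 450), runif(n, 50, 450))
  tf <- similarity_about_center(5, 0.98, 30, -12, center = c(250, 250))
  Q <- bonemorph:::tf_apply(bonemorph:::tf_inverse(tf), P)
  pairs <- data.frame(ref_x = P[, 1], ref_y = P[, 2],
                      mov_x = Q[, 1], mov_y = Q[, 2])
  est <- estimate_similarity(pairs)
  expect_lt(abs(est$rotation_deg - tf$rotation_deg), 1e-9)
  expect_lt(abs(est$scale - tf$scale), 1e-12)
  expect_lt(abs(est$dx - tf$dx) + abs(est$dy - tf$dy), 1e-8)
  expect_lt(est$rmse_px, 1e-9)
  # identity on aligned pairs
  id <- estimate_similarity(data.frame(ref_x = P[, 1], ref_y = P[, 2],
                                       mov_x = P[, 1], mov_y = P[, 2]))
  expect_equal(id$rotation_deg, 0)
  expect_equal(id$scale, 1)
  expect_error(estimate_similarity(data.frame(ref_x = c(1, 2), ref_y = c(1, 2),
                                              mov_x = c(3, 3), mov_y = c(4, 4))),
               "degenerate")

  # independent oracle: exhaustive grid over (rotation, scale), translation
  # solved in closed form per candidate, on noisy 10-bead clouds
  Qn <- Q + matrix(rnorm(2 * n, 0, 0.3), n, 2)
  pairs_n <- data.frame(ref_x = P[, 1], ref_y = P[, 2],
                        mov_x = Qn[, 1], mov_y = Qn[, 2])
  est_n <- estimate_similarity(pairs_n)
  best <- c(NA, NA); best_v <- Inf
  for (rot in seq(4, 6, by = 0.05)) for (s in seq(0.96, 1.0, by = 0.001)) {
    th <- bonemorph:::deg2rad(rot)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Qr <- s * Qn %*% t(R)
    t0 <- colMeans(P) - colMeans(Qr)
    v <- sum((P - sweep(Qr, 2, t0, `+`))^2)
    if (v < best_v) { best_v <- v; best <- c(rot, s) }
  }
  expect_lt(abs(est_n$rotation_deg - best[1]), 0.05)
  expect_lt(abs(est_n$scale - best[2]), 0.001)
})

test_that("parameter recovery holds over random transforms with noisy beads", {
  set.seed(33)
  errs <- matrix(NA_real_, 10, 3)
  for (i in 1:10) {
    rot <- runif(1, -30, 30); s <- runif(1, 0.9, 1.1)
    dx <- runif(1, -30, 30); dy <- runif(1, -30, 30)
    tf <- similarity_about_center(rot, s, dx, dy, center = c(250, 250))
    n <- 6
    P <- cbind(runif(n, 20, 480), runif(n, 20, 480))
    Q <- bonemorph:::tf_apply(bonemorph:::tf_inverse(tf), P) +
      matrix(rnorm(2 * n, 0, 0.5), n, 2)
    est <- estimate_similarity(data.frame(ref_x = P[, 1], ref_y = P[, 2],
                                          mov_x = Q[, 1], mov_y = Q[, 2]))
    # translation error measured as the transforms' disagreement at the
    # bead-cloud centroid (the physically meaningful shift)
    cbar <- matrix(colMeans(Q), 1)
    terr <- max(abs(bonemorph:::tf_apply(est, cbar) -
                    bonemorph:::tf_apply(tf, cbar)))
    errs[i, ] <- c(abs(est$rotation_deg - tf$rotation_deg),
                   abs(est$scale - tf$scale), terr)
  }
  expect_lt(max(errs[, 1]), 0.2)
  expect_lt(max(errs[, 2]), 0.005)
  expect_lt(max(errs[, 3]), 1)
})

test_that("fit accuracy improves with bead count at fixed noise (in expectation)", {
  set.seed(34)
  sigma <- 0.5
  stats <- sapply(c(4, 8, 16, 32), function(n) {
    reps <- replicate(60, {
      P <- cbind(runif(n, 0, 500), runif(n, 0, 500))
      Q <- P + matrix(rnorm(2 * n, 0, sigma), n, 2)
      est <- estimate_similarity(data.frame(ref_x = P[, 1], ref_y = P[, 2],
                                            mov_x = Q[, 1], mov_y = Q[, 2]))
      c(rot_err = abs(est$rotation_deg), rmse = est$rmse_px)
    })
    rowMeans(reps)
  })
  # recovered-parameter error shrinks with more beads ...
  expect_true(all(diff(stats["rot_err", ]) < 0))
  # ... while the residual stays bounded by the injected centroid noise
  expect_true(all(stats["rmse", ] < sigma * sqrt(2)))
})

test_that("warping undoes a known transform on the phantom", {
  ph <- make_trabecular_phantom(stripe_phantom_spec(
    seed = 35, beads = list(c(150, 150), c(850, 120), c(880, 650), c(120, 680))))
  tf <- similarity_about_center(3, 0.98, 6, -4, center = c(200, 150))
  moved <- apply_similarity(ph$stack, tf)
  ref_beads <- detect_beads(ph$stack$channels$label1, 6)
  mov_beads <- detect_beads(moved$channels$trap, 6, steps = 2)
  expect_gte(nrow(mov_beads), 3)
  pairs <- match_beads(ref_beads, mov_beads)
  est <- estimate_similarity(pairs)
  expect_lt(abs(est$rotation_deg - 3), 0.1)
  expect_lt(abs(est$scale - 0.98), 0.002)
  back <- warp_to_reference(moved, est)
  orig <- unclass(ph$stack$channels$trap)
  rec <- unclass(back$channels$trap)
  interior <- 40:260
  mae <- mean(abs(orig[interior, interior] - rec[interior, interior]))
  expect_lt(mae, 0.02 * diff(range(orig)))
  # beads in the warped channel land within 1 px of the reference beads
  warped_beads <- detect_beads(back$channels$trap, 6, steps = 2)
  D <- as.matrix(dist(rbind(as.matrix(ref_beads[, 1:2]),
                            as.matrix(warped_beads[, 1:2]))))
  nref <- nrow(ref_beads)
  nn <- apply(D[seq_len(nref), -seq_len(nref), drop = FALSE], 1, min)
  expect_lt(max(nn), 1)
  # identity warp leaves channels unchanged
  same <- warp_to_reference(ph$stack, similarity_transform())
  expect_identical(unclass(same$channels$trap), unclass(ph$stack$channels$trap))
})
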