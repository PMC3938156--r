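# Hand-built uniform stick field: every voxel one stick along `dir`.
uniform_field <- function(gs, dir, fraction = 0.6) {
  O <- array(0, c(gs, 3, 3))
  F_ <- array(0, c(gs, 3))
  for (i in 1:3) O[, , , 1, i] <- dir[i] / sqrt(sum(dir^2))
  F_[, , , 1] <- fraction
  truth <- list(orientations = O, fractions = F_,
                n_sticks = array(1L, gs), mask = array(1L, gs),
                S0 = 1000, d = 1.7e-3)
  stick_field_from_truth(truth)
}

test_that("direction interpolation honors threshold, sign and fixed points", {
  gs <- c(8, 8, 4)
  fld <- uniform_field(gs, c(1, 0, 0))
  cfg <- run_config()
  # uniform field: returns the previous direction
  w <- interpolate_direction(c(4, 4, 2), c(1, 0, 0), fld, cfg)
  expect_equal(w, c(1, 0, 0))
  # antipodal stick resolves toward the previous direction
  w2 <- interpolate_direction(c(4, 4, 2), c(-1, 0, 0), fld, cfg)
  expect_equal(w2, c(-1, 0, 0))
  # all fractions at/below the tracking threshold: no direction
  weak <- uniform_field(gs, c(1, 0, 0), fraction = 0.15)
  expect_null(interpolate_direction(c(4, 4, 2), c(1, 0, 0), weak, cfg))
  stickless <- uniform_field(gs, c(1, 0, 0), fraction = 0)
  stickless$n_sticks[] <- 0L
  expect_null(interpolate_direction(c(4, 4, 2), c(1, 0, 0), stickless, cfg))
})

test_that("streamlines keep the exact step size and angle contract", {
  sim <- straight_bundle_sim(gt55, snr = Inf, seed = 1)
  fld <- stick_field_from_truth(sim$truth)
  cfg <- run_config(n_seeds = 50, rng_seed = 3)
  tg <- seed_and_track(sim$truth$mask * 0L + sim$truth$mask, fld,
                       sim$truth$mask, cfg)
  expect_gt(length(tg), 0)
  for (m in tg$streamlines[seq_len(min(10, length(tg)))]) {
    steps <- diff(m)
    lens <- sqrt(rowSums(steps^2))
    expect_true(all(abs(lens - 0.2) < 1e-6))
    if (nrow(steps) > 1) {
      dots <- rowSums(steps[-1, , drop = FALSE] *
                        steps[-nrow(steps), , drop = FALSE]) / 0.04
      angles <- acos(pmin(1, pmax(-1, dots))) * 180 / pi
      expect_true(all(angles <= 60 + 1e-6))
    }
    expect_lte(nrow(m), 2 * cfg$max_steps + 1)
  }
})

test_that("straight bundles are tracked end to end, terminating out of mask", {
  sim <- straight_bundle_sim(gt55, snr = Inf, seed = 1)
  fld <- stick_field_from_truth(sim$truth)
  cfg <- run_config(n_seeds = 100, rng_seed = 5)
  # seed the bundle core: edge seeds exit the cylindrical mask laterally
  seed_mask <- array(0L, dim(sim$truth$mask))
  seed_mask[11:13, 6:7, 3:4] <- sim$truth$mask[11:13, 6:7, 3:4]
  tg <- seed_and_track(seed_mask, fld, sim$truth$mask, cfg)
  expect_equal(length(tg), 100)
  expect_true(all(tg$info$termination == "out_of_mask"))
  expect_true(all(tg$info$termination_bwd == "out_of_mask"))
  spans <- vapply(tg$streamlines, function(m) diff(range(m[, 1])), 1)
  expect_true(mean(spans > 15) >= 0.95)
})

test_that("turning-angle violations terminate; smooth bends are followed", {
  gs <- c(20, 10, 4)
  mask <- array(1L, gs)
  # a 70-degree disagreement between the launch direction and the eligible
  # neighbourhood exceeds the 60-degree threshold at the first step
  turn <- c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
  fld <- uniform_field(gs, turn)
  fld$orientations[6, 6, 3, 1, ] <- c(1, 0, 0)
  fld$fractions[6, 6, 3, 1] <- 0.14      # dominant but below the 0.15 gate
  tr <- propagate(c(5.9, 5.9, 2.5), fld, mask, run_config())
  expect_equal(tr$termination, "angle")
  expect_equal(tr$termination_bwd, "angle")

  # a smooth 70-degree bend spread over the interpolation cell is followed
  # (direction smoothing keeps each per-step turn below the threshold)
  fld2 <- uniform_field(gs, c(1, 0, 0))
  for (s in 1:3) fld2$orientations[11:20, , , 1, s] <- turn[s]
  tr2 <- propagate(c(5.5, 5.0, 2.0), fld2, mask, run_config())
  expect_equal(tr2$termination, "out_of_mask")
  steps <- diff(tr2$points)
  lens <- sqrt(rowSums(steps^2))
  dots <- rowSums(steps[-1, ] * steps[-nrow(steps), ]) / lens[-1] /
    lens[-length(lens)]
  expect_true(all(acos(pmin(1, dots)) * 180 / pi <= 60 + 1e-6))
})

test_that("seeding is reproducible, capped, and respects stickless masks", {
  sim <- straight_bundle_sim(gt55, snr = Inf, seed = 1)
  fld <- stick_field_from_truth(sim$truth)
  cfg <- run_config(n_seeds = 40, rng_seed = 9)
  t1 <- seed_and_track(sim$truth$mask, fld, sim$truth$mask, cfg)
  t2 <- seed_and_track(sim$truth$mask, fld, sim$truth$mask, cfg)
  expect_identical(t1$streamlines, t2$streamlines)
  expect_lte(length(t1), 40)
  # stickless seed mask yields no streamlines
  bare <- fld
  bare$n_sticks[] <- 0L
  t3 <- seed_and_track(sim$truth$mask, bare, sim$truth$mask, cfg)
  expect_equal(length(t3), 0)
  expect_equal(attr(t3, "n_discarded"), 40)
  expect_error(seed_and_track(array(0L, dim(sim$truth$mask)), fld,
                              sim$truth$mask, cfg), "empty seed mask")
})

test_that("sub-threshold curvature is tracked end to end", {
  # quarter-circle bundle with gentle curvature
  theta <- seq(0, pi / 2, length.out = 25)
  ctrline <- cbind(4 + 14 * sin(theta), 4 + 14 * (1 - cos(theta)), 3)
  sim <- simulate_subject(list(fiber_bundle(ctrline, radius = 1.6,
                                            stick_fraction = 0.6)),
                          c(22, 22, 6), gt20, snr = Inf, rng_seed = 2)
  fld <- stick_field_from_truth(sim$truth)
  cfg <- run_config(n_seeds = 100, rng_seed = 4)
  # seed near the arc midpoint
  seed_mask <- array(0L, dim(sim$truth$mask))
  g <- as.matrix(expand.grid(x = 1:22 - 0.5, y = 1:22 - 0.5, z = 1:6 - 0.5))
  fine <- cbind(4 + 14 * sin(seq(0, pi / 2, length.out = 200)),
                4 + 14 * (1 - cos(seq(0, pi / 2, length.out = 200))), 3)
  mind <- apply(g, 1, function(p) min(sqrt(colSums((t(fine) - p)^2))))
  core <- array(as.integer(mind <= 0.8), c(22, 22, 6))
  mid <- round(c(4 + 14 * sin(pi / 4), 4 + 14 * (1 - cos(pi / 4))))
  seed_mask[mid[1] + (-1:1), mid[2] + (-1:1), ] <-
    core[mid[1] + (-1:1), mid[2] + (-1:1), ]
  tg <- seed_and_track(seed_mask, fld, sim$truth$mask, cfg)
  arc_len <- vapply(tg$streamlines, function(m)
    0.2 * (nrow(m) - 1), 1)
  # full quarter circle is ~22 voxels of arc; accept >= 70%
  expect_gte(mean(arc_len > 15), 0.95)
})
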