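test_that("ball-and-stick forward model matches its closed form", {
  # pure ball with b*d = 1
  expect_equal(ball_stick_signal(1000, 1000, c(0, 1, 0), list(), 1e-3),
               1000 * exp(-1))
  # one stick perpendicular to the gradient: no attenuation
  expect_equal(ball_stick_signal(500, 1000, c(1, 0, 0),
                                 list(list(v = c(0, 1, 0), f = 1)), 1.7e-3),
               500)
  # one stick parallel to the gradient
  expect_equal(ball_stick_signal(1000, 1000, c(1, 0, 0),
                                 list(list(v = c(1, 0, 0), f = 1)), 1.7e-3),
               1000 * exp(-1.7))
  # b = 0 returns S0 regardless of sticks
  expect_equal(ball_stick_signal(750, 0, c(1, 0, 0),
                                 list(list(v = c(0, 0, 1), f = 0.5)), 1.7e-3),
               750)
  expect_error(ball_stick_signal(1000, 1000, c(1, 0, 0),
                                 list(list(v = c(1, 0, 0), f = 1.2)), 1e-3),
               "fraction")
})

test_that("signal decreases monotonically with |g.v| for a single stick", {
  v <- c(0, 0, 1)
  cosines <- seq(0, 1, length.out = 21)
  s <- vapply(cosines, function(cc) {
    g <- c(sqrt(1 - cc^2), 0, cc)
    ball_stick_signal(1000, 1000, g, list(list(v = v, f = 0.7)), 1.7e-3)
  }, 1)
  expect_true(all(diff(s) < 0))
})

test_that("Rician noise has the right magnitude floor in air voxels", {
  sim <- straight_bundle_sim(gt20, snr = 20, seed = 3,
                             grid_shape = c(30, 30, 10))
  air <- sim$truth$S0_map == 0
  samples <- as.numeric(sim$dwi$data[,,,1][air])
  for (k in 2:21) samples <- c(samples, as.numeric(sim$dwi$data[,,,k][air]))
  expect_gt(length(samples), 1e5)
  sigma <- 1000 / 20
  expect_equal(mean(samples), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("the generators are bit-identical under a fixed seed", {
  a <- straight_bundle_sim(gt20, snr = 25, seed = 99)
  b <- straight_bundle_sim(gt20, snr = 25, seed = 99)
  expect_identical(a$dwi$data, b$dwi$data)
  expect_identical(a$truth$orientations, b$truth$orientations)
  c1 <- make_crossing_phantom(60, gtab = gt20, snr = 30, rng_seed = 5)
  c2 <- make_crossing_phantom(60, gtab = gt20, snr = 30, rng_seed = 5)
  expect_identical(c1$dwi$data, c2$dwi$data)
})

test_that("noise-free signals equal the forward model exactly", {
  sim <- straight_bundle_sim(gt55, snr = Inf, seed = 1)
  v <- c(12L, 6L, 3L)  # 0-based voxel well inside the bundle
  tr <- sim$truth
  k <- tr$n_sticks[v[1] + 1, v[2] + 1, v[3] + 1]
  expect_equal(k, 1L)
  ori <- tr$orientations[v[1] + 1, v[2] + 1, v[3] + 1, 1, ]
  f <- tr$fractions[v[1] + 1, v[2] + 1, v[3] + 1, 1]
  expected <- vapply(seq_len(nrow(gt55)), function(i) {
    ball_stick_signal(1000, gt55$bval[i],
                      c(gt55$gx[i], gt55$gy[i], gt55$gz[i]),
                      list(list(v = ori, f = f)), 1.7e-3)
  }, 1)
  expect_equal(sim$dwi$data[v[1] + 1, v[2] + 1, v[3] + 1, ], expected,
               tolerance = 1e-12)
})

test_that("frame dropout is injected at the stated rate and recorded", {
  sim <- straight_bundle_sim(gt55, snr = Inf, seed = 7,
                             grid_shape = c(16, 10, 6))
  expect_length(sim$truth$outlier_frames, 0)
  sim2 <- simulate_subject(
    list(fiber_bundle(rbind(c(2, 5, 3), c(14, 5, 3)))),
    c(16, 10, 6), gt55, snr = Inf, outlier_rate = 0.1, rng_seed = 7)
  n_out <- length(sim2$truth$outlier_frames)
  # binomial(55, 0.1): essentially always within [0, 14]
  expect_gt(n_out, 0)
  expect_lt(n_out, 15)
  # flagged frames really are attenuated
  v <- c(9, 6, 4)  # 1-based in-bundle voxel
  k <- sim2$truth$outlier_frames[1]
  expect_lt(sim2$dwi$data[v[1], v[2], v[3], k],
            0.7 * sim$dwi$data[v[1], v[2], v[3], k])
})

test_that("crossing phantoms have the stated geometry and masks", {
  ph <- make_crossing_phantom(90, c(0.4, 0.4), gtab = gt20, snr = Inf,
                              rng_seed = 1)
  ctr <- dim(ph$truth$n_sticks) / 2
  i <- ctr[1]; j <- ctr[2]; k <- ceiling(ctr[3])
  expect_equal(ph$truth$n_sticks[i, j, k], 2L)
  o1 <- ph$truth$orientations[i, j, k, 1, ]
  o2 <- ph$truth$orientations[i, j, k, 2, ]
  expect_lt(abs(axis_angle(o1, o2) - 90), 0.5)
  # ball fraction 1 - 0.4 - 0.4 in the crossing region
  expect_equal(sum(ph$truth$fractions[i, j, k, ]), 0.8)
  caps <- ph$truth$end_caps
  expect_true(all(vapply(caps, sum, 1) >= 1))
  overlap <- caps$A_start * caps$A_end + caps$A_start * caps$B_start +
    caps$A_start * caps$B_end + caps$A_end * caps$B_start +
    caps$A_end * caps$B_end + caps$B_start * caps$B_end
  expect_equal(sum(overlap), 0)
})

test_that("cohorts have the study's group sizes and the stated degradation", {
  coh <- simulate_cohort(n_per_group = c(14, 15), effect = 0.3,
                         grid_shape = c(20, 20, 6), gtab = gt20,
                         snr = Inf, rng_seed = 2)
  expect_length(coh$subjects, 29)
  expect_equal(sum(coh$covariates$group == "A"), 14)
  expect_equal(sum(coh$covariates$group == "B"), 15)
  subA <- coh$subjects[[which(coh$covariates$group == "A")[1]]]
  subB <- coh$subjects[[which(coh$covariates$group == "B")[1]]]
  fmax <- function(s) max(s$truth$fractions)
  expect_equal(fmax(subA), 0.6)
  expect_equal(fmax(subB), 0.6)          # intact pathways keep baseline
  # the degraded pathway's bundle runs at 0.6 * (1 - 0.3) = 0.42
  expect_true(any(abs(subB$truth$fractions - 0.42) < 1e-9))
  expect_false(any(abs(subA$truth$fractions - 0.42) < 1e-9))
  # masks are disjoint
  tm <- subA$truth$target_masks
  expect_equal(max(Reduce(`+`, tm) + subA$truth$seed_mask), 1L)
  # null cohort: no degraded fractions anywhere
  coh0 <- simulate_cohort(n_per_group = c(2, 2), effect = 0,
                          grid_shape = c(20, 20, 6), gtab = gt20,
                          snr = Inf, rng_seed = 3)
  for (s in coh0$subjects) {
    expect_true(all(s$truth$fractions %in% c(0, 0.6)))
  }
})
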