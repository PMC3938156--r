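test_that("local windows have the documented layouts and shrink at edges", {
  expect_equal(nrow(window_offsets("eleven")), 11)
  expect_equal(nrow(window_offsets("face")), 7)
  expect_equal(nrow(window_offsets("cube")), 27)

  sim <- straight_bundle_sim(gt55, snr = Inf, seed = 1)
  full <- array(1L, dim(sim$truth$mask))
  win <- build_window(sim$dwi, full, gt55, c(12L, 6L, 3L))
  expect_equal(dim(win$data), c(11, 55))

  # mask-edge centre: members outside the mask are dropped
  win_edge <- build_window(sim$dwi, sim$truth$mask, gt55, c(2L, 6L, 3L))
  expect_lt(nrow(win_edge$data), 11)
  expect_gte(nrow(win_edge$data), 3)

  # members with zero baseline signal (air) are dropped
  air_adjacent <- build_window(sim$dwi, full, gt55, c(1L, 6L, 3L))
  expect_lt(nrow(air_adjacent$data), 11)

  # a fully isolated centre degenerates
  lonely <- array(0L, dim(sim$truth$mask))
  lonely[13, 7, 4] <- 1L
  expect_error(build_window(sim$dwi, lonely, gt55, c(12L, 6L, 3L)),
               class = "dentract_window_degenerate")
  expect_error(build_window(sim$dwi, lonely, gt55, c(0L, 0L, 0L)),
               "inside the mask")
})

test_that("source decomposition finds one source for rank-1 windows and two for crossings", {
  # rank-1: all rows proportional to a single stick profile
  p <- stick_profile(gt55, c(1, 0, 0), f = 0.6)
  X <- outer(c(1, 0.9, 1.1, 0.95, 1.05), p)
  win <- list(data = X)
  src <- decompose_sources(win, max_components = 3, rng_seed = 1)
  expect_length(src, 1)
  expect_gt(abs(cor(src[[1]], p)), 0.999)

  # max_components caps at rank
  src3 <- decompose_sources(win, max_components = 3, rng_seed = 2)
  expect_lte(length(src3), 2)

  # noise-free two-bundle crossing: sources span both true profiles
  p1 <- stick_profile(gt55, c(1, 0, 0), f = 1)
  p2 <- stick_profile(gt55, c(0, 1, 0), f = 1)
  mix <- rbind(0.8 * p1 + 0.2 * p2, 0.5 * p1 + 0.5 * p2,
               0.2 * p1 + 0.8 * p2, 0.65 * p1 + 0.35 * p2,
               0.35 * p1 + 0.65 * p2, 0.9 * p1 + 0.1 * p2)
  src2 <- decompose_sources(list(data = mix), max_components = 3,
                            rng_seed = 3)
  expect_equal(length(src2), 2)
  S <- do.call(cbind, src2)
  cos_dist <- function(y) {
    proj <- S %*% qr.coef(qr(S), y)
    1 - abs(sum(proj * y)) / sqrt(sum(proj^2) * sum(y^2))
  }
  expect_lt(cos_dist(p1), 0.05)
  expect_lt(cos_dist(p2), 0.05)
})

test_that("single-stick fits recover orientation, ignore scale, reject flat profiles", {
  v <- c(0.3, -0.7, 0.5) / sqrt(sum(c(0.3, -0.7, 0.5)^2))
  prof <- stick_profile(gt55, v, f = 1)
  st <- fit_single_stick(prof, gt55)
  expect_lt(axis_angle(st$v, v), 0.5)
  expect_equal(st$d, 1.7e-3, tolerance = 1e-3)
  # scale invariance of the recovered orientation
  st2 <- fit_single_stick(0.37 * prof, gt55)
  expect_lt(axis_angle(st2$v, st$v), 1e-6)
  # antipodal canonicalisation: first nonzero coordinate positive
  expect_gt(st$v[which(abs(st$v) > 1e-12)[1]], 0)
  # flat profile: no stick
  expect_null(fit_single_stick(rep(0.5, 55), gt55))
})

test_that("noise-free single-bundle voxels are fit essentially exactly", {
  sim <- straight_bundle_sim(gt55, snr = Inf, seed = 1)
  ent <- fit_voxel_icabsm(sim$dwi, sim$truth$mask, gt55, c(12L, 6L, 3L),
                          run_config())
  expect_length(ent$fractions, 1)
  expect_lt(abs(ent$fractions[1] - 0.6), 0.02)
  expect_lt(axis_angle(ent$orientations[1, ], c(1, 0, 0)), 1)
  expect_equal(ent$fractions[1] + ent$ball_fraction, 1, tolerance = 1e-6)
  expect_equal(ent$d, 1.7e-3, tolerance = 1e-3)
})

test_that("ball-only voxels yield no sticks", {
  # background voxel inside the object but outside every bundle
  sim <- straight_bundle_sim(gt55, snr = Inf, seed = 1)
  bg_mask <- sim$truth$object_mask
  bg_mask[sim$truth$mask > 0] <- 0L
  ctr <- c(12L, 2L, 3L)
  expect_equal(sim$truth$n_sticks[13, 3, 4], 0L)
  ent <- fit_voxel_icabsm(sim$dwi, bg_mask, gt55, ctr, run_config())
  expect_length(ent$fractions, 0)
  expect_equal(ent$ball_fraction, 1)
})

test_that("orientation estimates are antipodally invariant", {
  sim <- straight_bundle_sim(gt55, snr = Inf, seed = 1)
  # reversing the centerline flips every true tangent sign
  rev_sim <- simulate_subject(
    list(fiber_bundle(rbind(c(22, 6, 3), c(2, 6, 3)), radius = 1.6,
                      stick_fraction = 0.6)),
    c(24, 12, 6), gt55, snr = Inf, rng_seed = 1)
  expect_identical(sim$dwi$data, rev_sim$dwi$data)
  e1 <- fit_voxel_icabsm(sim$dwi, sim$truth$mask, gt55, c(12L, 6L, 3L),
                         run_config())
  e2 <- fit_voxel_icabsm(rev_sim$dwi, rev_sim$truth$mask, gt55,
                         c(12L, 6L, 3L), run_config())
  expect_equal(e1$orientations, e2$orientations, tolerance = 1e-6)
  expect_equal(e1$fractions, e2$fractions, tolerance = 1e-6)
})

test_that("whole-field fits are rotation-equivariant at 90 degrees", {
  sim <- straight_bundle_sim(gt20, snr = Inf, seed = 6,
                             grid_shape = c(14, 14, 6))
  cfg <- run_config()
  f1 <- fit_stick_field(sim$dwi, sim$truth$mask, gt20, cfg)
  rot_xy <- function(a) {
    d <- dim(a)
    aperm(a, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  nd <- dim(sim$dwi$data)
  rdata <- array(0, c(nd[2], nd[1], nd[3], nd[4]))
  for (k in seq_len(nd[4])) rdata[, , , k] <- rot_xy(sim$dwi$data[, , , k])
  rmask <- rot_xy(array(sim$truth$mask, dim(sim$truth$mask)))
  rgt <- gradient_table(gt20$bval, cbind(-gt20$gy, gt20$gx, gt20$gz))
  f2 <- fit_stick_field(dwi_volume(rdata, c(1.88, 1.88, 3)), rmask, rgt, cfg)
  # a voxel deep inside the bundle maps (i,j,k) -> (nd2-1-j, i, k) 0-based
  v <- c(7L, 7L, 3L)
  rv <- c(nd[2] - 1L - v[2], v[1], v[3])
  o1 <- f1$orientations[v[1] + 1, v[2] + 1, v[3] + 1, 1, ]
  o2 <- f2$orientations[rv[1] + 1, rv[2] + 1, rv[3] + 1, 1, ]
  rot_o1 <- c(-o1[2], o1[1], o1[3])
  expect_lt(axis_angle(o2, rot_o1), 2)
})

test_that("no-stick density counts stickless mask voxels", {
  sim <- straight_bundle_sim(gt20, snr = Inf, seed = 8,
                             grid_shape = c(14, 10, 6))
  cfg <- run_config()
  # fibered mask: every voxel carries a stick
  f_fib <- fit_stick_field(sim$dwi, sim$truth$mask, gt20, cfg)
  expect_equal(f_fib$no_stick_density, 0)
  # all-background mask: density 1
  bg <- sim$truth$object_mask
  bg[sim$truth$mask > 0] <- 0L
  bg[, , c(1, 6)] <- 0L       # keep windows off the object boundary
  f_bg <- fit_stick_field(sim$dwi, bg, gt20, cfg)
  expect_equal(f_bg$no_stick_density, 1)
  # mixed mask: density = (#stickless)/(#mask), cross-checked against truth
  mixed <- sim$truth$mask
  mixed[bg > 0] <- 1L
  f_mx <- fit_stick_field(sim$dwi, mixed, gt20, cfg)
  expected <- sum(mixed > 0 & sim$truth$n_sticks == 0L) / sum(mixed > 0)
  expect_equal(f_mx$no_stick_density, expected, tolerance = 1e-12)
  expect_equal(f_mx$no_stick_density,
               sum(f_mx$n_sticks[mixed > 0] == 0L) / sum(mixed > 0))
})

test_that("fractions stay in [0,1] and sum to one with the ball", {
  reps <- 0
  for (seed in 1:5) {
    ph <- make_crossing_phantom(60, c(0.35, 0.35), gtab = gt30, snr = 25,
                                rng_seed = seed)
    cfg <- run_config(rng_seed = seed)
    ent <- fit_voxel_icabsm(ph$dwi, ph$truth$mask, gt30, c(12L, 12L, 2L),
                            cfg)
    expect_true(all(ent$fractions >= 0 & ent$fractions <= 1))
    expect_equal(sum(ent$fractions) + ent$ball_fraction, 1,
                 tolerance = 1e-6)
    expect_lte(length(ent$fractions), 3)
    reps <- reps + 1
  }
  expect_equal(reps, 5)
})
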