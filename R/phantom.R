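#' Ball-and-stick forward signal for one gradient
#'
#' The multi-compartment ball-and-stick model: an isotropic "ball"
#' compartment plus up to three perfectly anisotropic "stick" compartments
#' sharing one diffusivity,
#' \deqn{S = S_0 [(1 - \sum_j f_j) e^{-bd} + \sum_j f_j e^{-bd (g \cdot v_j)^2}].}
#'
#' @param S0 Baseline (b = 0) signal.
#' @param b b-value (s/mm^2).
#' @param g Unit gradient direction (length-3).
#' @param sticks List of `list(v = unit 3-vector, f = fraction)` entries
#'   (may be empty).
#' @param d Diffusivity (mm^2/s) shared by ball and sticks.
#' @return Scalar signal in `(0, S0]`; equals `S0` when `b = 0`.
#' @examples
#' ball_stick_signal(1000, 1000, c(1, 0, 0), list(), 1e-3)  # pure ball
#' @export
ball_stick_signal <- function(S0, b, g, sticks, d) {
  fs <- vapply(sticks, function(s) s$f, 1)
  if (length(fs) && (any(fs < 0) || sum(fs) > 1 + 1e-9)) {
    abort("stick fractions must be nonnegative and sum to at most 1.")
  }
  if (b < 0) abort("b must be nonnegative.")
  att <- (1 - sum(fs)) * exp(-b * d)
  for (s in sticks) {
    proj <- sum(unit(g) * unit(s$v))
    att <- att + s$f * exp(-b * d * proj^2)
  }
  S0 * att
}

# Vectorised forward model over a gradient table for one voxel.
# orientations: k x 3 matrix; fractions: length k.
ball_stick_profile <- function(gtab, orientations, fractions, d, S0) {
  b <- gtab$bval
  att <- (1 - sum(fractions)) * exp(-b * d)
  if (length(fractions)) {
    G <- bvec_matrix(gtab)
    for (j in seq_along(fractions)) {
      proj <- G %*% orientations[j, ]
      att <- att + fractions[j] * exp(-b * d * proj[, 1]^2)
    }
  }
  S0 * att
}

#' Specify a fiber bundle for the phantom generator
#'
#' @param centerline Matrix (>= 2 rows) of 3D points in voxel coordinates.
#' @param radius Bundle radius in voxels.
#' @param stick_fraction Stick volume fraction inside the bundle, in `[0, 1]`.
#' @param diffusivity Diffusivity (mm^2/s); `NA` inherits the phantom default.
#' @param dispersion_deg Per-voxel random angular dispersion of the true
#'   orientation about the bundle tangent (degrees, SD); models loss of
#'   directional coherence.
#' @return A `fiber_bundle` spec.
#' @export
fiber_bundle <- function(centerline, radius = 1.5, stick_fraction = 0.6,
                         diffusivity = NA, dispersion_deg = 0) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2 || ncol(centerline) != 3) {
    abort("centerline needs >= 2 rows of 3D points.")
  }
  if (radius <= 0) abort("radius must be positive.")
  if (stick_fraction < 0 || stick_fraction > 1) abort("fraction outside [0, 1].")
  structure(list(centerline = centerline, radius = radius,
                 stick_fraction = stick_fraction, diffusivity = diffusivity,
                 dispersion_deg = dispersion_deg),
            class = "fiber_bundle")
}

# Densify a polyline to roughly `spacing`-length segments.
densify_polyline <- function(pts, spacing = 0.25) {
  out <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- vnorm(b - a)
    n <- max(1, ceiling(len / spacing))
    tt <- seq_len(n) / n
    out[[i + 1]] <- cbind(a[1] + tt * (b[1] - a[1]),
                          a[2] + tt * (b[2] - a[2]),
                          a[3] + tt * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

# Rasterize bundles onto a grid: per-voxel orientations (up to 3) + fractions.
rasterize_bundles <- function(bundles, grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  ctr <- as.matrix(expand.grid(x = seq_len(nx) - 0.5,
                               y = seq_len(ny) - 0.5,
                               z = seq_len(nz) - 0.5))
  nvox <- nrow(ctr)
  O <- array(0, c(nx, ny, nz, 3, 3))
  F_ <- array(0, c(nx, ny, nz, 3))
  nst <- array(0L, c(nx, ny, nz))
  bid <- array(0L, c(nx, ny, nz, 3))
  for (bi in seq_along(bundles)) {
    bd <- bundles[[bi]]
    poly <- densify_polyline(bd$centerline)
    nseg <- nrow(poly) - 1
    best_d2 <- rep(Inf, nvox)
    best_tan <- matrix(0, nvox, 3)
    for (s in seq_len(nseg)) {
      a <- poly[s, ]; b2 <- poly[s + 1, ]
      ab <- b2 - a
      len2 <- sum(ab^2)
      if (len2 == 0) next
      ap <- sweep(ctr, 2, a)
      tt <- pmin(1, pmax(0, (ap %*% ab)[, 1] / len2))
      dx <- ap - outer(tt, ab)
      d2 <- rowSums(dx^2)
      better <- d2 < best_d2
      if (any(better)) {
        best_d2[better] <- d2[better]
        best_tan[better, ] <- matrix(ab / sqrt(len2), sum(better), 3,
                                     byrow = TRUE)
      }
    }
    inside <- which(best_d2 <= bd$radius^2)
    for (v in inside) {
      i <- arrayInd(v, c(nx, ny, nz))
      k <- nst[i[1], i[2], i[3]] + 1L
      if (k > 3L) abort("more than 3 bundles overlap in one voxel.")
      O[i[1], i[2], i[3], k, ] <- canonical_axis(best_tan[v, ])
      F_[i[1], i[2], i[3], k] <- bd$stick_fraction
      bid[i[1], i[2], i[3], k] <- bi
      nst[i[1], i[2], i[3]] <- k
    }
  }
  tot <- apply(F_, 1:3, sum)
  if (any(tot > 1 + 1e-9)) {
    abort("overlapping bundle fractions exceed 1 in at least one voxel.")
  }
  list(orientations = O, fractions = F_, n_sticks = nst, bundle_id = bid)
}

# Random angular perturbation of unit vector `v` with SD `sd_rad` (radians).
perturb_axis <- function(v, sd_rad) {
  e1 <- unit(if (abs(v[1]) < 0.9) cross3(v, c(1, 0, 0)) else
    cross3(v, c(0, 1, 0)))
  e2 <- cross3(v, e1)
  z <- rnorm(2, sd = tan(sd_rad))
  canonical_axis(unit(v + z[1] * e1 + z[2] * e2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Precompute the mm-space sample grid for rigid resampling on `dims`.
rigid_grid <- function(dims, voxel_dims) {
  g <- as.matrix(expand.grid(x = seq_len(dims[1]) - 0.5,
                             y = seq_len(dims[2]) - 0.5,
                             z = seq_len(dims[3]) - 0.5))
  list(mm_centered = sweep(sweep(g, 2, voxel_dims, `*`), 2,
                           dims / 2 * voxel_dims),
       ctr_mm = dims / 2 * voxel_dims)
}

# Resample one 3D frame under a rigid transform (tx,ty,tz mm; rx,ry,rz rad
# about the volume centre): output(x) = input(R (x - c) + c + t) in mm.
apply_rigid <- function(arr, params, voxel_dims, grid = NULL) {
  R <- euler_rotation(params[4], params[5], params[6])
  apply_rigid_matrix(arr, R, params[1:3], voxel_dims, grid)
}

# As apply_rigid but with an explicit rotation matrix (used for exact
# inverse transforms).
apply_rigid_matrix <- function(arr, R, t, voxel_dims, grid = NULL) {
  dims <- dim(arr)
  grid <- grid %||% rigid_grid(dims, voxel_dims)
  src <- grid$mm_centered %*% t(R)
  src <- sweep(src, 2, grid$ctr_mm + t, `+`)
  vox <- sweep(src, 2, voxel_dims, `/`)
  array(trilinear(arr, vox, fill = 0), dims)
}

#' Simulate one subject's diffusion acquisition from bundle specs
#'
#' Generates the noise-free ball-and-stick signal on the grid, then injects,
#' in order: rigid head motion per diffusion-weighted frame (a smooth random
#' walk in all six rigid parameters, scaled by `motion_amplitude`), sporadic
#' whole-frame signal dropout (each b > 0 frame independently scaled by a
#' factor drawn from U(0.2, 0.6) with probability `outlier_rate`), and Rician
#' noise (magnitude of complex Gaussian with channel sigma `S0 / snr`).
#' Everything injected is recorded in the returned truth object.
#'
#' @param bundles List of [fiber_bundle()] specs.
#' @param grid_shape Integer length-3 grid size.
#' @param gtab A [gradient_table()].
#' @param snr Signal-to-noise ratio `S0 / sigma`; `Inf` for noise-free.
#' @param motion_amplitude Scale of the motion random walk (0 = static). The
#'   resulting motion index is approximately equal to this value.
#' @param outlier_rate Per-frame dropout probability.
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @param voxel_dims Voxel size in mm.
#' @param S0 Baseline signal.
#' @param d Diffusivity (mm^2/s) for ball and sticks.
#' @param object `"ellipsoid"` places the signal inside a head-like
#'   ellipsoid (air outside), giving every frame the spatial structure a
#'   real acquisition has; `"full"` fills the whole grid.
#' @return A list with elements `dwi` (a [dwi_volume()]) and `truth` (a list
#'   holding per-voxel true orientations/fractions, the bundle mask, the
#'   injected motion trace, the outlier frame list, and the model constants).
#' @export
simulate_subject <- function(bundles, grid_shape, gtab, snr = 30,
                             motion_amplitude = 0, outlier_rate = 0,
                             rng_seed = 1, voxel_dims = c(1.88, 1.88, 3),
                             S0 = 1000, d = 1.7e-3,
                             object = c("ellipsoid", "full")) {
  stopifnot(snr > 0)
  object <- match.arg(object)
  ras <- rasterize_bundles(bundles, grid_shape)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  nf <- nrow(gtab)
  G <- bvec_matrix(gtab)
  S0_map <- array(S0, grid_shape)
  if (object == "ellipsoid") {
    ax <- pmax(grid_shape / 2 - 1, 1)
    g <- as.matrix(expand.grid(seq_len(nx) - 0.5, seq_len(ny) - 0.5,
                               seq_len(nz) - 0.5))
    rel <- sweep(sweep(g, 2, grid_shape / 2), 2, ax, `/`)
    S0_map[rowSums(rel^2) > 1] <- 0
  }
  dwi_idx <- which(gtab$bval > 0)
  motion_trace <- matrix(0, nf, 6)
  outlier_frames <- integer()
  data <- NULL
  with_local_seed(rng_seed, {
    # per-voxel orientation dispersion for bundles that request it
    disp <- vapply(bundles, function(b) b$dispersion_deg %||% 0, 1)
    if (any(disp > 0)) {
      for (j in 1:3) {
        sel <- which(ras$bundle_id[, , , j] > 0L &
                       disp[pmax(ras$bundle_id[, , , j], 1L)] > 0)
        for (v in sel) {
          idx <- arrayInd(v, c(nx, ny, nz))
          sd_rad <- disp[ras$bundle_id[idx[1], idx[2], idx[3], j]] * pi / 180
          ras$orientations[idx[1], idx[2], idx[3], j, ] <-
            perturb_axis(ras$orientations[idx[1], idx[2], idx[3], j, ], sd_rad)
        }
      }
    }
    ftot <- apply(ras$fractions, 1:3, sum)
    clean <- array(0, c(nx, ny, nz, nf))
    for (k in seq_len(nf)) {
      b <- gtab$bval[k]
      att <- (1 - ftot) * exp(-b * d)
      for (j in 1:3) {
        fj <- ras$fractions[, , , j]
        if (all(fj == 0)) next
        proj <- ras$orientations[, , , j, 1] * G[k, 1] +
          ras$orientations[, , , j, 2] * G[k, 2] +
          ras$orientations[, , , j, 3] * G[k, 3]
        att <- att + fj * exp(-b * d * proj^2)
      }
      clean[, , , k] <- S0_map * att
    }
    data <- clean
    if (motion_amplitude > 0) {
      steps <- matrix(rnorm(length(dwi_idx) * 6), ncol = 6)
      walk <- apply(steps, 2, cumsum)
      walk <- sweep(walk, 2, c(rep(0.4, 3), rep(0.02, 3)) * motion_amplitude,
                    `*`)
      motion_trace[dwi_idx, ] <- walk
      for (i in seq_along(dwi_idx)) {
        k <- dwi_idx[i]
        data[, , , k] <- apply_rigid(data[, , , k], walk[i, ], voxel_dims)
      }
    }
    if (outlier_rate > 0) {
      hit <- runif(length(dwi_idx)) < outlier_rate
      outlier_frames <- dwi_idx[hit]
      for (k in outlier_frames) {
        data[, , , k] <- data[, , , k] * runif(1, 0.2, 0.6)
      }
    }
    if (is.finite(snr)) {
      sigma <- S0 / snr
      e1 <- array(rnorm(length(data), sd = sigma), dim(data))
      e2 <- array(rnorm(length(data), sd = sigma), dim(data))
      data <- sqrt((data + e1)^2 + e2^2)
    }
  })
  outside <- S0_map == 0
  if (any(outside & ras$n_sticks > 0L)) {
    ras$n_sticks[outside] <- 0L
    for (j in 1:3) {
      fj <- ras$fractions[, , , j]; fj[outside] <- 0
      ras$fractions[, , , j] <- fj
    }
  }
  truth <- list(orientations = ras$orientations, fractions = ras$fractions,
                n_sticks = ras$n_sticks, mask = (ras$n_sticks > 0) * 1L,
                S0_map = S0_map, object_mask = (S0_map > 0) * 1L,
                motion_trace = motion_trace, outlier_frames = outlier_frames,
                S0 = S0, d = d)
  list(dwi = dwi_volume(data, voxel_dims = voxel_dims), truth = truth)
}

#' Two straight bundles crossing at a known angle
#'
#' Builds a phantom with two in-plane bundles crossing at `angle_deg` in the
#' central region, plus four disjoint end-cap ROI masks usable as seed and
#' target regions.
#'
#' @param angle_deg Crossing angle in degrees, in `(0, 90]`.
#' @param fractions Length-2 stick fractions of the two bundles.
#' @param grid_shape Grid size (default `c(24, 24, 5)`).
#' @param gtab Gradient table (default the 55-direction scheme).
#' @param snr Signal-to-noise ratio.
#' @param rng_seed Seed.
#' @param ... Passed to [simulate_subject()].
#' @return As [simulate_subject()], with `truth$end_caps` (named list of four
#'   masks) and `truth$bundle_axes` added.
#' @export
make_crossing_phantom <- function(angle_deg, fractions = c(0.4, 0.4),
                                  grid_shape = c(24, 24, 5),
                                  gtab = default_gradient_table(),
                                  snr = 30, rng_seed = 1, ...) {
  stopifnot(angle_deg > 0, angle_deg <= 90)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  ctr <- c(nx, ny, nz) / 2
  half <- angle_deg / 2 * pi / 180
  u1 <- c(cos(half), sin(half), 0)
  u2 <- c(cos(half), -sin(half), 0)
  ext <- min(nx, ny) / 2 - 1.5
  mk <- function(u, f) fiber_bundle(rbind(ctr - ext * u, ctr + ext * u),
                                    radius = 1.6, stick_fraction = f)
  b1 <- mk(u1, fractions[1])
  b2 <- mk(u2, fractions[2])
  sim <- simulate_subject(list(b1, b2), grid_shape, gtab, snr = snr,
                          rng_seed = rng_seed, ...)
  cap <- function(p) {
    m <- array(0L, grid_shape)
    g <- as.matrix(expand.grid(seq_len(nx) - 0.5, seq_len(ny) - 0.5,
                               seq_len(nz) - 0.5))
    idx <- which(sqrt(rowSums(sweep(g, 2, p)^2)) <= 1.8)
    m[idx] <- 1L
    m
  }
  caps <- list(A_start = cap(ctr - (ext - 0.6) * u1),
               A_end = cap(ctr + (ext - 0.6) * u1),
               B_start = cap(ctr - (ext - 0.6) * u2),
               B_end = cap(ctr + (ext - 0.6) * u2))
  sim$truth$end_caps <- caps
  sim$truth$bundle_axes <- rbind(canonical_axis(u1), canonical_axis(u2))
  sim
}

# Geometry of the cerebellum-like phantom: a curved seed ribbon per side
# connected to two target blobs (dorsal/ventral dentate surrogates).
cerebellum_layout <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  zmid <- nz / 2
  arc <- function(x0, sgn) {
    y <- seq(ny * 0.28, ny * 0.72, length.out = 7)
    x <- x0 + sgn * 1.6 * sin((y - min(y)) / (max(y) - min(y)) * pi)
    cbind(x, y, zmid)
  }
  left_arc <- arc(3.5, 1)
  right_arc <- arc(nx - 3.5, -1)
  tgt <- list(L_DDN = c(nx * 0.38, ny * 0.62, zmid),
              L_VDN = c(nx * 0.38, ny * 0.38, zmid),
              R_DDN = c(nx * 0.62, ny * 0.62, zmid),
              R_VDN = c(nx * 0.62, ny * 0.38, zmid))
  bundle_path <- function(a_idx, side_arc, target) {
    start <- side_arc[a_idx, ]
    mid <- (start + c(target[1], target[2], zmid)) / 2
    mid[2] <- mid[2] + 1.2 * sign(target[2] - start[2])
    rbind(start, mid, c(target[1], target[2], zmid))
  }
  paths <- list(L_DDN = bundle_path(5, left_arc, tgt$L_DDN),
                L_VDN = bundle_path(3, left_arc, tgt$L_VDN),
                R_DDN = bundle_path(5, right_arc, tgt$R_DDN),
                R_VDN = bundle_path(3, right_arc, tgt$R_VDN))
  list(left_arc = left_arc, right_arc = right_arc, targets = tgt,
       paths = paths, zmid = zmid)
}

#' Cerebellum-like phantom: seed ribbon with four target pathways
#'
#' A desk-scale stand-in for the seed/target layout of the clinical study:
#' one curved seed ribbon per hemisphere (posterior-lateral cerebellar
#' cortex surrogate) connected by curved bundles to two small target blobs
#' per side (dorsal and ventral dentate surrogates, named `L_DDN`, `L_VDN`,
#' `R_DDN`, `R_VDN`). One pathway's stick fraction can be degraded by
#' `effect` to emulate reduced fiber coherence.
#'
#' @param grid_shape Grid size (default `c(36, 36, 8)`).
#' @param gtab Gradient table.
#' @param effect Fractional reduction of the degraded pathway's stick
#'   fraction, in `[0, 1)`.
#' @param degraded_pathway Which pathway to degrade (default `"R_VDN"`).
#' @param dispersion_deg Orientation dispersion (degrees, SD) added to the
#'   degraded pathway; models reduced directional coherence.
#' @param base_fraction Stick fraction of intact bundles.
#' @param snr,rng_seed,... Passed to [simulate_subject()].
#' @return As [simulate_subject()], with `truth$seed_mask` and
#'   `truth$target_masks` (named list of four disjoint masks) added.
#' @export
make_cerebellum_phantom <- function(grid_shape = c(36, 36, 8),
                                    gtab = default_gradient_table(),
                                    effect = 0, degraded_pathway = "R_VDN",
                                    dispersion_deg = 0,
                                    base_fraction = 0.6, snr = 30,
                                    rng_seed = 1, ...) {
  lay <- cerebellum_layout(grid_shape)
  frac <- function(nm) if (nm == degraded_pathway)
    base_fraction * (1 - effect) else base_fraction
  bundles <- purrr::imap(lay$paths, function(p, nm)
    fiber_bundle(p, radius = 1.4, stick_fraction = frac(nm),
                 dispersion_deg = if (nm == degraded_pathway)
                   dispersion_deg else 0))
  sim <- simulate_subject(unname(bundles), grid_shape, gtab, snr = snr,
                          rng_seed = rng_seed, ...)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  g <- as.matrix(expand.grid(seq_len(nx) - 0.5, seq_len(ny) - 0.5,
                             seq_len(nz) - 0.5))
  blob <- function(p, r) {
    m <- array(0L, grid_shape)
    m[sqrt(rowSums(sweep(g, 2, p)^2)) <= r] <- 1L
    m
  }
  seed_mask <- array(0L, grid_shape)
  for (a in list(lay$left_arc, lay$right_arc)) {
    poly <- densify_polyline(a)
    for (i in seq_len(nrow(poly))) {
      sel <- sqrt(rowSums(sweep(g, 2, poly[i, ])^2)) <= 1.4
      seed_mask[sel] <- 1L
    }
  }
  targets <- purrr::map(lay$targets, ~ blob(c(.x[1], .x[2], lay$zmid), 1.6))
  # targets must be disjoint from each other and from the seed
  for (nm in names(targets)) targets[[nm]][seed_mask == 1L] <- 0L
  sim$truth$seed_mask <- seed_mask
  sim$truth$target_masks <- targets
  sim$truth$degraded_pathway <- if (effect > 0) degraded_pathway else NA
  sim$truth$effect <- effect
  sim
}

#' Simulate a two-group imaging cohort with known ground truth
#'
#' Generates one cerebellum-like phantom per subject. Group B subjects have
#' the designated pathway's stick fraction reduced by `effect`; ages are
#' drawn uniformly from `age_range`; per-subject motion amplitudes are drawn
#' from group-specific normal distributions (truncated at 0); dropout frames
#' are injected at a group-specific rate. All injected values are recorded.
#'
#' @param n_per_group Length-2 integer: subjects in groups A and B
#'   (default `c(14, 15)`, the study's TD/ASD sizes).
#' @param effect Stick-fraction reduction applied to group B (default 0.3).
#' @param dispersion_deg Orientation dispersion (degrees, SD) added to the
#'   degraded pathway in group B, modelling the hypothesized loss of
#'   directional coherence (default 20).
#' @param degraded_pathway Pathway degraded in group B.
#' @param age_range Uniform age range in years.
#' @param motion_mean,motion_sd Length-2 (A, B) motion-amplitude normal
#'   parameters; defaults mirror the study's motion indices (2.00/1.12).
#' @param outlier_rate Length-2 per-frame dropout rates (A, B).
#' @param grid_shape,gtab,snr Phantom geometry and noise.
#' @param rng_seed Master seed; per-subject seeds derive from it.
#' @return A list with `subjects` (list of [make_cerebellum_phantom()]
#'   results) and `covariates` (tibble: subject, group, age,
#'   true_motion_amplitude, outlier_rate).
#' @export
simulate_cohort <- function(n_per_group = c(14, 15), effect = 0.3,
                            dispersion_deg = 20,
                            degraded_pathway = "R_VDN",
                            age_range = c(3.6, 14.0),
                            motion_mean = c(2.00, 1.12),
                            motion_sd = c(0.67, 0.63),
                            outlier_rate = c(0.091, 0.072),
                            grid_shape = c(36, 36, 8),
                            gtab = default_gradient_table(),
                            snr = 30, rng_seed = 1) {
  stopifnot(all(n_per_group >= 2))
  n_tot <- sum(n_per_group)
  grp <- rep(c("A", "B"), n_per_group)
  covar <- with_local_seed(rng_seed, {
    tibble(subject = sprintf("S%02d", seq_len(n_tot)),
           group = grp,
           age = runif(n_tot, age_range[1], age_range[2]),
           true_motion_amplitude = pmax(0, rnorm(
             n_tot,
             mean = ifelse(grp == "A", motion_mean[1], motion_mean[2]),
             sd = ifelse(grp == "A", motion_sd[1], motion_sd[2]))),
           outlier_rate = ifelse(grp == "A", outlier_rate[1],
                                 outlier_rate[2]),
           seed = sample.int(2^31 - 2, n_tot))
  })
  subjects <- purrr::map(seq_len(n_tot), function(i) {
    make_cerebellum_phantom(
      grid_shape = grid_shape, gtab = gtab,
      effect = if (grp[i] == "B") effect else 0,
      dispersion_deg = if (grp[i] == "B") dispersion_deg else 0,
      degraded_pathway = degraded_pathway,
      snr = snr, rng_seed = covar$seed[i],
      motion_amplitude = covar$true_motion_amplitude[i],
      outlier_rate = covar$outlier_rate[i])
  })
  names(subjects) <- covar$subject
  list(subjects = subjects, covariates = dplyr::select(covar, -"seed"),
       gtab = gtab)
}
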