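#' Local window layouts for the multi-fiber fit
#'
#' The default "eleven" layout is the centre voxel, its six face neighbours,
#' and its four in-slice diagonal neighbours — an 11-voxel neighbourhood that
#' favours in-plane context, reflecting anisotropic voxels with thick slices.
#' `"face"` is centre + 6; `"cube"` is the full 3x3x3 block.
#'
#' @param layout One of `"eleven"`, `"face"`, `"cube"`.
#' @return Integer offset matrix (rows are x, y, z offsets).
#' @export
window_offsets <- function(layout = c("eleven", "face", "cube")) {
  layout <- match.arg(layout)
  face <- rbind(c(0, 0, 0),
                c(1, 0, 0), c(-1, 0, 0),
                c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  switch(layout,
         face = face,
         eleven = rbind(face,
                        c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0)),
         cube = as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)))
}

#' Build the local diffusion data matrix around a voxel
#'
#' Rows are the diffusion-weighted attenuations `S/S0` of each window member
#' across the b > 0 gradients. Members outside the mask or grid, or with
#' non-positive baseline signal, are dropped (the window may shrink).
#'
#' @param vol A [dwi_volume()].
#' @param mask 3D binary analysis mask.
#' @param gtab Matching [gradient_table()].
#' @param center Integer length-3, 0-based voxel index (must be in mask).
#' @param layout Window layout name (see [window_offsets()]).
#' @return A list: `data` (rows x gradients attenuation matrix), `members`
#'   (0-based voxel indices), `center`. Errors with class
#'   `dentract_window_degenerate` if fewer than 3 usable rows remain.
#' @export
build_window <- function(vol, mask, gtab, center,
                         layout = "eleven") {
  gs <- grid_shape(vol)
  if (mask[center[1] + 1, center[2] + 1, center[3] + 1] <= 0) {
    abort("window centre must lie inside the mask.")
  }
  off <- window_offsets(layout)
  b0 <- gtab$bval == 0
  dwi <- !b0
  rows <- list(); members <- list()
  for (r in seq_len(nrow(off))) {
    v <- center + off[r, ]
    if (any(v < 0) || any(v >= gs)) next
    if (mask[v[1] + 1, v[2] + 1, v[3] + 1] <= 0) next
    sig <- vol$data[v[1] + 1, v[2] + 1, v[3] + 1, ]
    s0 <- mean(sig[b0])
    if (!is.finite(s0) || s0 <= 0) next
    rows[[length(rows) + 1]] <- sig[dwi] / s0
    members[[length(members) + 1]] <- v
  }
  if (length(rows) < 3) {
    abort("degenerate window: fewer than 3 usable rows.",
          class = "dentract_window_degenerate")
  }
  list(data = do.call(rbind, rows),
       members = do.call(rbind, members),
       center = center)
}

# Deflationary FastICA with the logcosh (smooth, even) contrast.
# X: mixtures in rows (m x G). Returns unmixing rows applied to the
# *uncentered* data so source profiles keep their positive mean, or NULL on
# non-convergence.
fastica_profiles <- function(X, k, rng_seed, max_iter = 500, tol = 1e-6) {
  m <- nrow(X)
  Xc <- X - rowMeans(X)
  C <- Xc %*% t(Xc) / ncol(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  k <- min(k, sum(ev > 1e-12 * max(ev, 1e-300)))
  if (k < 1) return(NULL)
  E <- e$vectors[, seq_len(k), drop = FALSE]
  Dm <- diag(1 / sqrt(ev[seq_len(k)]), k)
  K <- Dm %*% t(E)                       # whitening: Z = K Xc (k x G)
  Z <- K %*% Xc
  W <- matrix(0, k, k)
  init <- with_local_seed(rng_seed, matrix(rnorm(k * k), k, k))
  for (i in seq_len(k)) {
    w <- unit(init[, i])
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      u <- drop(crossprod(w, Z))
      gu <- tanh(u)
      gpu <- 1 - gu^2
      w_new <- Z %*% gu / ncol(Z) - mean(gpu) * w
      if (i > 1) {
        Wp <- W[seq_len(i - 1), , drop = FALSE]
        w_new <- w_new - t(Wp) %*% (Wp %*% w_new)
      }
      w_new <- unit(drop(w_new))
      if (abs(abs(sum(w_new * w)) - 1) < tol) {
        w <- w_new
        converged <- TRUE
        break
      }
      w <- w_new
    }
    if (!converged) return(NULL)
    W[i, ] <- w
  }
  # Unmixing in original mixture space, applied to uncentered rows
  U <- W %*% K                           # k x m
  P <- U %*% X                           # k x G source profiles (+ means)
  P
}

#' Decompose a local window into independent attenuation sources
#'
#' PCA on the window's data matrix decides how many components to keep
#' (eigenvalue share >= 5%, capped at `max_components` and at the matrix
#' rank), then deflationary FastICA with a smooth even contrast separates
#' the independent attenuation profiles. Each profile is sign-normalized to
#' nonnegative mean and scaled to unit maximum. Falls back to the PCA
#' components if ICA fails to converge. Deterministic for a fixed seed.
#'
#' @param window Output of [build_window()].
#' @param max_components Upper bound on retained sources (<= 3 recommended).
#' @param rng_seed Seed for the ICA initialisation.
#' @param evr_threshold Minimum eigenvalue share for a component.
#' @return List of numeric profiles (one per source, length = number of
#'   b > 0 gradients).
#' @export
decompose_sources <- function(window, max_components = 3, rng_seed = 1,
                              evr_threshold = 0.05) {
  X <- window$data
  m <- nrow(X)
  max_components <- min(max_components, m - 1)
  Xc <- X - rowMeans(X)
  C <- Xc %*% t(Xc) / ncol(X)
  ev <- pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0)
  tot <- sum(ev)
  k <- if (tot <= 1e-18) 1L else sum(ev / tot >= evr_threshold)
  k <- max(1L, min(k, max_components))
  P <- fastica_profiles(X, k, rng_seed)
  if (is.null(P)) {
    # PCA fallback, same normalization
    e <- eigen(C, symmetric = TRUE)
    U <- t(e$vectors[, seq_len(k), drop = FALSE])
    P <- U %*% X
  }
  lapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]
    if (mean(p) < 0) p <- -p
    mx <- max(abs(p))
    if (mx > 0) p <- p / mx
    p
  })
}

# Design for log-profile tensor on b>0 frames (no intercept column removed).
profile_design <- function(gtab) {
  dwi <- gtab$bval > 0
  tensor_design(gtab)[dwi, , drop = FALSE]
}

sph_to_vec <- function(theta, phi) {
  theta <- unname(theta); phi <- unname(phi)
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}
vec_to_sph <- function(v) {
  v <- unit(v)
  c(theta = acos(min(1, max(-1, v[3]))), phi = atan2(v[2], v[1]))
}

#' Fit a single stick compartment to one attenuation profile
#'
#' Least-squares fit of `c * exp(-b d (g . v)^2)` to the profile over the
#' b > 0 gradients. The orientation is initialised from the principal
#' eigenvector of the log-profile tensor and refined numerically; the
#' result is antipodally canonical (first nonzero coordinate positive) and
#' invariant to scaling of the profile.
#'
#' @param profile Attenuation per b > 0 gradient (positive).
#' @param gtab The full [gradient_table()].
#' @return `list(v, d, scale)` or `NULL` for a flat (isotropic) profile.
#' @export
fit_single_stick <- function(profile, gtab) {
  dwi <- gtab$bval > 0
  G <- bvec_matrix(gtab)[dwi, , drop = FALSE]
  b <- gtab$bval[dwi]
  y <- pmax(profile, 1e-8)
  if (sd(y) / mean(y) < 1e-7) return(NULL)      # flat: no direction
  X <- profile_design(gtab)
  beta <- qr.coef(qr(X), log(y))
  beta[is.na(beta)] <- 0
  M <- beta_to_tensor(beta)$D
  e <- eigen(M, symmetric = TRUE)
  v0 <- e$vectors[, 1]
  d0 <- max(e$values[1], 1e-5)
  sp <- vec_to_sph(v0)
  obj <- function(par) {
    v <- sph_to_vec(par[1], par[2])
    d <- exp(par[3])
    q2 <- drop(G %*% v)^2
    mdl <- exp(-b * d * q2)
    # optimal scale in closed form
    cc <- sum(mdl * y) / sum(mdl^2)
    sum((y - cc * mdl)^2)
  }
  fit <- optim(c(sp[1], sp[2], log(d0)), obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-12))
  v <- canonical_axis(sph_to_vec(fit$par[1], fit$par[2]))
  d <- unname(exp(fit$par[3]))
  if (d < 1e-6) return(NULL)                    # effectively isotropic
  q2 <- drop(G %*% v)^2
  mdl <- exp(-b * d * q2)
  list(v = v, d = d, scale = sum(mdl * y) / sum(mdl^2))
}

# Nonnegative least squares by Lawson-Hanson active set (small problems).
nnls_small <- function(A, y) {
  n <- ncol(A)
  passive <- logical(n)
  x <- numeric(n)
  w <- drop(crossprod(A, y - A %*% x))
  for (outer in seq_len(3 * n + 10)) {
    cand <- which(!passive & w > 1e-12)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z <- qr.coef(qr(Ap), y)
      z[is.na(z)] <- 0
      if (all(z > 1e-12)) {
        x[] <- 0; x[passive] <- z
        break
      }
      xp <- x[passive]
      neg <- z <= 1e-12
      alpha <- min(xp[neg] / (xp[neg] - z[neg] + 1e-300))
      xfull <- numeric(n); xfull[passive] <- xp + alpha * (z - xp)
      x <- xfull
      passive <- passive & x > 1e-12
      if (!any(passive)) break
    }
    w <- drop(crossprod(A, y - A %*% x))
  }
  x
}

# Constrained fraction fit at one voxel: orientations fixed, shared d.
# Returns list(fractions, d, resid).
fit_fractions <- function(a, gtab, orientations, d_init) {
  dwi <- gtab$bval > 0
  G <- bvec_matrix(gtab)[dwi, , drop = FALSE]
  b <- gtab$bval[dwi]
  y <- a
  k <- nrow(orientations)
  solve_at_d <- function(d) {
    ball <- exp(-b * d)
    cols <- vapply(seq_len(k), function(j) {
      q2 <- drop(G %*% orientations[j, ])^2
      exp(-b * d * q2) - ball
    }, numeric(length(b)))
    f <- nnls_small(as.matrix(cols), y - ball)
    if (sum(f) > 1) f <- f / sum(f)
    pred <- ball + as.matrix(cols) %*% f
    list(f = f, resid = sum((y - pred)^2))
  }
  opt <- optimize(function(ld) solve_at_d(exp(ld))$resid,
                  interval = log(c(2e-4, 3.5e-3)), tol = 1e-6)
  d <- exp(opt$minimum)
  sol <- solve_at_d(d)
  list(fractions = sol$f, d = d, resid = sol$resid)
}

# Refine one stick orientation against the centre attenuation, holding the
# other compartments fixed.
refine_orientation <- function(a, gtab, orientations, fractions, d, j) {
  dwi <- gtab$bval > 0
  G <- bvec_matrix(gtab)[dwi, , drop = FALSE]
  b <- gtab$bval[dwi]
  ball <- (1 - sum(fractions)) * exp(-b * d)
  fixed <- ball
  for (jj in seq_len(nrow(orientations))) {
    if (jj == j) next
    q2 <- drop(G %*% orientations[jj, ])^2
    fixed <- fixed + fractions[jj] * exp(-b * d * q2)
  }
  sp <- vec_to_sph(orientations[j, ])
  obj <- function(par) {
    v <- sph_to_vec(par[1], par[2])
    q2 <- drop(G %*% v)^2
    sum((a - fixed - fractions[j] * exp(-b * d * q2))^2)
  }
  fit <- optim(sp, obj, method = "Nelder-Mead",
               control = list(maxit = 200, reltol = 1e-10))
  canonical_axis(sph_to_vec(fit$par[1], fit$par[2]))
}

# Single-tensor fallback for degenerate windows: one stick along the
# principal eigenvector with the voxel's FA as its fraction.
tensor_fallback_entry <- function(vol, gtab, center) {
  sig <- vol$data[center[1] + 1, center[2] + 1, center[3] + 1, ]
  tv <- fit_tensor_robust(sig, gtab, reject_threshold = Inf)
  l <- tv$eigenvalues
  f <- min(1, max(0, fa(l[1], l[2], l[3])))
  if (!tv$valid || f < 1e-3) {
    return(list(orientations = matrix(0, 0, 3), fractions = numeric(),
                ball_fraction = 1, d = mean(l), S0 = tv$S0_fit,
                fallback = TRUE))
  }
  list(orientations = matrix(canonical_axis(tv$eigenvectors[, 1]), 1, 3),
       fractions = f, ball_fraction = 1 - f, d = l[1], S0 = tv$S0_fit,
       fallback = TRUE)
}

#' Multi-fiber fit of one voxel by alternating ICA and ball-and-stick steps
#'
#' Decomposes the voxel's local window into up to 3 independent attenuation
#' sources, fits a single stick to each source, then alternates between (a)
#' constrained least-squares refit of all volume fractions (and the shared
#' diffusivity) of the full ball-and-stick model at the centre voxel with
#' orientations fixed and (b) per-stick orientation refinement, until the
#' fractions change by less than 1e-3 or 10 iterations. Sticks with a
#' fraction below `config$min_stick_fraction` are pruned and the remaining
#' fractions renormalized with the ball to sum to 1.
#'
#' @param vol A [dwi_volume()].
#' @param mask 3D binary analysis mask.
#' @param gtab Matching [gradient_table()].
#' @param center 0-based voxel index.
#' @param config A [run_config()].
#' @return A stick-field entry: `orientations` (k x 3, antipodally
#'   canonical), `fractions` (length k), `ball_fraction`, `d`, `S0`.
#' @export
fit_voxel_icabsm <- function(vol, mask, gtab, center, config = run_config()) {
  win <- tryCatch(build_window(vol, mask, gtab, center,
                               layout = config$window_layout),
                  dentract_window_degenerate = function(e) NULL)
  if (is.null(win)) return(tensor_fallback_entry(vol, gtab, center))
  b0 <- gtab$bval == 0
  sig <- vol$data[center[1] + 1, center[2] + 1, center[3] + 1, ]
  S0 <- mean(sig[b0])
  a <- sig[!b0] / S0
  seed <- (as.numeric(config$rng_seed) +
             7919 * (center[1] + 101 * center[2] + 10007 * center[3])) %%
    2147483646 + 1
  sources <- decompose_sources(win, max_components = 3, rng_seed = seed)
  sticks <- purrr::compact(purrr::map(sources, fit_single_stick, gtab = gtab))
  if (!length(sticks)) {
    d_iso <- max(1e-5, -mean(log(pmax(a, 1e-8))) / mean(gtab$bval[!b0]))
    return(list(orientations = matrix(0, 0, 3), fractions = numeric(),
                ball_fraction = 1, d = d_iso, S0 = S0, fallback = FALSE))
  }
  orientations <- do.call(rbind, purrr::map(sticks, "v"))
  d <- median(purrr::map_dbl(sticks, "d"))
  if (nrow(orientations) == 1L) {
    # Crossing bundles can collapse into one source when the window members
    # mix them in near-identical proportions; offer the centre voxel's
    # secondary tensor axis as an extra candidate. The constrained fraction
    # fit keeps it only if it earns a fraction above the prune threshold.
    X <- profile_design(gtab)
    beta <- qr.coef(qr(X), log(pmax(a, 1e-8)))
    beta[is.na(beta)] <- 0
    e2 <- eigen(beta_to_tensor(beta)$D, symmetric = TRUE)$vectors[, 2]
    if (axial_angle_deg(e2, orientations[1, ]) > 10) {
      orientations <- rbind(orientations, canonical_axis(e2))
    }
  }
  f_old <- rep(-1, nrow(orientations))
  for (it in seq_len(10)) {
    sol <- fit_fractions(a, gtab, orientations, d)
    f <- sol$fractions
    d <- sol$d
    if (max(abs(f - f_old)) < 1e-3) break
    f_old <- f
    for (j in seq_len(nrow(orientations))) {
      if (f[j] > 1e-3) {
        orientations[j, ] <- refine_orientation(a, gtab, orientations, f, d, j)
      }
    }
  }
  keep <- f >= config$min_stick_fraction
  orientations <- orientations[keep, , drop = FALSE]
  if (any(keep)) {
    sol <- fit_fractions(a, gtab, orientations, d)
    f <- sol$fractions
    d <- sol$d
  } else {
    f <- numeric()
  }
  tot <- sum(f)
  if (tot > 1) { f <- f / tot; tot <- 1 }
  list(orientations = orientations, fractions = f,
       ball_fraction = 1 - tot, d = d, S0 = S0, fallback = FALSE)
}

#' Fit the stick field over a whole mask
#'
#' Runs [fit_voxel_icabsm()] at every mask voxel and reports the no-stick
#' density: the fraction of mask voxels in which no stick compartment
#' survived the fit (an index of lost fiber coherence when measured over a
#' structure of interest).
#'
#' @inheritParams fit_voxel_icabsm
#' @return A `stick_field`: arrays `orientations` (x,y,z,3,3),
#'   `fractions` (x,y,z,3), `ball_fraction`, `d`, `S0`, `n_sticks`, plus
#'   `mask`, `no_stick_density` and `n_fallback`.
#' @export
fit_stick_field <- function(vol, mask, gtab, config = run_config()) {
  gs <- grid_shape(vol)
  stopifnot(all(dim(mask) == gs))
  O <- array(0, c(gs, 3, 3))
  F_ <- array(0, c(gs, 3))
  ball <- array(1, gs)
  dmap <- array(0, gs)
  s0 <- array(0, gs)
  nst <- array(0L, gs)
  idx <- which(mask > 0, arr.ind = TRUE)
  n_fallback <- 0L
  for (r in seq_len(nrow(idx))) {
    ijk <- idx[r, ] - 1L
    ent <- fit_voxel_icabsm(vol, mask, gtab, ijk, config)
    k <- length(ent$fractions)
    i <- idx[r, 1]; j <- idx[r, 2]; z <- idx[r, 3]
    if (k > 0) {
      O[i, j, z, seq_len(k), ] <- ent$orientations
      F_[i, j, z, seq_len(k)] <- ent$fractions
    }
    ball[i, j, z] <- ent$ball_fraction
    dmap[i, j, z] <- ent$d
    s0[i, j, z] <- ent$S0
    nst[i, j, z] <- k
    if (isTRUE(ent$fallback)) n_fallback <- n_fallback + 1L
  }
  n_mask <- nrow(idx)
  density <- if (n_mask) sum(nst[mask > 0] == 0L) / n_mask else 1
  structure(list(orientations = O, fractions = F_, ball_fraction = ball,
                 d = dmap, S0 = s0, n_sticks = nst, mask = mask,
                 no_stick_density = density, n_fallback = n_fallback,
                 grid_shape = gs),
            class = "stick_field")
}

#' @export
print.stick_field <- function(x, ...) {
  cat(sprintf(
    "<stick_field> %s grid, %d mask voxels, no-stick density %.3f\n",
    paste(x$grid_shape, collapse = "x"), sum(x$mask > 0),
    x$no_stick_density))
  invisible(x)
}

#' Build a single-stick field from a tensor fit
#'
#' One stick per voxel along the tensor's principal eigenvector with the
#' voxel's FA as its fraction — the classical single-tensor tracking field
#' used as the baseline the multi-fiber method is compared against.
#'
#' @param maps Output of [compute_scalar_maps()].
#' @param mask 3D binary mask.
#' @return A `stick_field`.
#' @export
stick_field_from_tensor <- function(maps, mask) {
  gs <- dim(maps$fa)
  O <- array(0, c(gs, 3, 3))
  F_ <- array(0, c(gs, 3))
  O[, , , 1, ] <- maps$tensor_evecs
  F_[, , , 1] <- maps$fa * (mask > 0)
  nst <- array(0L, gs)
  nst[maps$fa > 0 & mask > 0] <- 1L
  n_mask <- sum(mask > 0)
  structure(list(orientations = O, fractions = F_,
                 ball_fraction = 1 - apply(F_, 1:3, sum),
                 d = maps$ad, S0 = array(1, gs), n_sticks = nst,
                 mask = mask,
                 no_stick_density = if (n_mask) sum(nst[mask > 0] == 0) /
                   n_mask else 1,
                 n_fallback = 0L, grid_shape = gs),
            class = "stick_field")
}

#' Build a stick field directly from known ground truth
#'
#' @param truth The `truth` element of a phantom simulation.
#' @return A `stick_field` holding the true orientations and fractions.
#' @export
stick_field_from_truth <- function(truth) {
  gs <- dim(truth$n_sticks)
  structure(list(orientations = truth$orientations,
                 fractions = truth$fractions,
                 ball_fraction = 1 - apply(truth$fractions, 1:3, sum),
                 d = array(truth$d, gs), S0 = array(truth$S0, gs),
                 n_sticks = truth$n_sticks, mask = truth$mask,
                 no_stick_density = NA_real_, n_fallback = 0L,
                 grid_shape = gs),
            class = "stick_field")
}
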