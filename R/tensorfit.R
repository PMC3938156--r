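#' Fractional anisotropy, axial and radial diffusivity
#'
#' Standard tensor-derived scalars:
#' \deqn{FA = \sqrt{1/2}\,\sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2
#'   + (\lambda_1-\lambda_3)^2} / \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2},}
#' `AD = lambda1`, `RD = (lambda2 + lambda3)/2`. FA of the all-zero tensor is
#' defined as 0.
#'
#' @param l1,l2,l3 Eigenvalues (any order; FA/AD/RD are symmetric apart from
#'   AD/RD which use the sorted values).
#' @return Scalar.
#' @examples
#' fa(1.7e-3, 0.3e-3, 0.3e-3)  # ~0.799
#' @export
fa <- function(l1, l2, l3) {
  ss <- l1^2 + l2^2 + l3^2
  num <- (l1 - l2)^2 + (l2 - l3)^2 + (l1 - l3)^2
  # tensors with all eigenvalues below 1e-9 mm^2/s are numerically zero
  ifelse(ss < 1e-18, 0, sqrt(0.5) * sqrt(num) / sqrt(ss))
}

#' @rdname fa
#' @export
ad <- function(l1, l2, l3) pmax(l1, l2, l3)

#' @rdname fa
#' @export
rd <- function(l1, l2, l3) {
  mx <- pmax(l1, l2, l3)
  (l1 + l2 + l3 - mx) / 2
}

# Design matrix for log S = X beta, beta = (log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor_design <- function(gtab) {
  G <- bvec_matrix(gtab)
  b <- gtab$bval
  cbind(1,
        -b * G[, 1]^2, -b * G[, 2]^2, -b * G[, 3]^2,
        -2 * b * G[, 1] * G[, 2], -2 * b * G[, 1] * G[, 3],
        -2 * b * G[, 2] * G[, 3])
}

# Nonlinear LS fit of S = exp(X beta) by Gauss-Newton with step halving,
# initialised from the log-linear fit. Returns beta.
nls_tensor <- function(y, X, max_iter = 50, tol = 1e-12) {
  ylog <- log(pmax(y, 1e-10))
  beta <- qr.coef(qr(X), ylog)
  beta[is.na(beta)] <- 0
  sse <- function(b) sum((y - exp(pmin(X %*% b, 50)))^2)
  cur <- sse(beta)
  for (it in seq_len(max_iter)) {
    eta <- exp(pmin(X %*% beta, 50))[, 1]
    r <- y - eta
    J <- X * eta                      # d eta / d beta = eta * X
    step <- tryCatch(qr.coef(qr(J), r), error = function(e) NULL)
    if (is.null(step)) break
    step[is.na(step)] <- 0
    lam <- 1
    repeat {
      cand <- beta + lam * step
      new <- sse(cand)
      if (new <= cur || lam < 1e-6) break
      lam <- lam / 2
    }
    if (new > cur) break
    conv <- (cur - new) <= tol * (cur + 1e-30)
    beta <- cand
    cur <- new
    if (conv) break
  }
  beta
}

beta_to_tensor <- function(beta) {
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  list(S0 = exp(beta[1]), D = D)
}

#' Detect whole-frame signal dropouts from the robust fit's rejections
#'
#' A frame rejected by the voxel-wise robust tensor fit in a majority of
#' mask voxels is a whole-frame artifact (pulsation or motion-related
#' dropout) rather than a local one. Such frames should also be excluded
#' from the multi-fiber decomposition, which has no outlier model of its
#' own. Operates on the per-frame rejection fractions that
#' [compute_scalar_maps()] aggregates.
#'
#' @param maps Output of [compute_scalar_maps()].
#' @param min_fraction Minimum fraction of valid mask voxels rejecting the
#'   frame.
#' @return Integer vector of frame indices (into the acquisition).
#' @export
detect_outlier_frames <- function(maps, min_fraction = 0.3) {
  fr <- maps$frame_rejection_fraction
  which(fr >= min_fraction)
}

#' Robust voxel-wise tensor fit with iterative outlier rejection
#'
#' Implements the robust-estimation loop used for artifact-contaminated
#' clinical data: fit the single-tensor model by equal-weight nonlinear
#' least squares, flag measurements whose residual exceeds
#' `reject_threshold` robust standard deviations (median absolute deviation
#' scaled by 1.4826), refit on the retained set, and repeat until the flag
#' set stabilizes (max 10 iterations). The final fit is an ordinary
#' nonlinear least-squares fit on the retained measurements. b = 0 frames
#' are never rejected. The tensor is projected to positive semidefinite by
#' clamping negative eigenvalues to zero.
#'
#' @param signals Per-frame signal vector.
#' @param gtab Matching [gradient_table()].
#' @param reject_threshold Rejection threshold in robust-sigma units;
#'   `Inf` reduces to a plain nonlinear least-squares fit.
#' @return A list: `eigenvalues` (sorted descending), `eigenvectors`
#'   (columns, matching order), `S0_fit`, `outlier_flags` (logical per
#'   frame), `valid`.
#' @export
fit_tensor_robust <- function(signals, gtab, reject_threshold = 3.0) {
  stopifnot(length(signals) == nrow(gtab))
  X <- tensor_design(gtab)
  n <- length(signals)
  b0 <- gtab$bval == 0
  keep <- rep(TRUE, n)
  if (sum(keep) < 7) {
    return(invalid_tensor(n))
  }
  beta <- NULL
  for (it in seq_len(10)) {
    if (sum(keep) < 7) break
    beta <- nls_tensor(signals[keep], X[keep, , drop = FALSE])
    if (!is.finite(reject_threshold)) break
    res <- signals - exp(pmin(X %*% beta, 50))[, 1]
    sig <- mad(res[keep & !b0], constant = 1.4826)
    if (!is.finite(sig)) break
    # relative floor so exact fits don't flag numerically-zero residuals
    sig <- max(sig, 1e-9 * mean(abs(signals[keep])))
    new_keep <- b0 | abs(res) <= reject_threshold * sig
    if (sum(new_keep) < 7) break     # keep previous retained set
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  if (sum(keep) < 7 || is.null(beta)) return(invalid_tensor(n))
  beta <- nls_tensor(signals[keep], X[keep, , drop = FALSE])
  tf <- beta_to_tensor(beta)
  e <- eigen(tf$D, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  list(eigenvalues = ev, eigenvectors = e$vectors, S0_fit = tf$S0,
       outlier_flags = !keep, valid = TRUE)
}

invalid_tensor <- function(n) {
  list(eigenvalues = c(0, 0, 0), eigenvectors = diag(3), S0_fit = NA_real_,
       outlier_flags = rep(FALSE, n), valid = FALSE)
}

#' Voxel-wise FA/AD/RD scalar maps with outlier-fraction map
#'
#' Fits the robust tensor in every mask voxel and assembles FA, AD, RD and
#' the per-voxel fraction of rejected diffusion-weighted measurements.
#' Values outside the mask are 0. The mask-average outlier fraction is a
#' per-subject quality statistic.
#'
#' @param vol A [dwi_volume()].
#' @param gtab Matching [gradient_table()].
#' @param mask 3D binary array matching the volume grid.
#' @param reject_threshold Passed to [fit_tensor_robust()].
#' @return A list of 3D arrays `fa`, `ad`, `rd`, `outlier_fraction`, plus
#'   `mean_outlier_fraction`, `n_invalid`, and `tensor_evecs` (x,y,z,3
#'   principal eigenvector field) with `tensor_fa` duplicate of `fa`.
#' @export
compute_scalar_maps <- function(vol, gtab, mask,
                                reject_threshold = 3.0) {
  gs <- grid_shape(vol)
  stopifnot(all(dim(mask) == gs))
  fa_map <- array(0, gs); ad_map <- array(0, gs); rd_map <- array(0, gs)
  out_map <- array(0, gs)
  evec <- array(0, c(gs, 3))
  idx <- which(mask > 0, arr.ind = TRUE)
  n_invalid <- 0L
  ndwi <- sum(gtab$bval > 0)
  frame_rej <- numeric(nrow(gtab))
  n_valid <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    tv <- fit_tensor_robust(vol$data[i, j, k, ], gtab, reject_threshold)
    if (!tv$valid) {
      n_invalid <- n_invalid + 1L
      next
    }
    frame_rej <- frame_rej + tv$outlier_flags
    n_valid <- n_valid + 1L
    l <- tv$eigenvalues
    fa_map[i, j, k] <- fa(l[1], l[2], l[3])
    ad_map[i, j, k] <- ad(l[1], l[2], l[3])
    rd_map[i, j, k] <- rd(l[1], l[2], l[3])
    out_map[i, j, k] <- sum(tv$outlier_flags) / ndwi
    evec[i, j, k, ] <- canonical_axis(tv$eigenvectors[, 1])
  }
  nmask <- nrow(idx)
  list(fa = fa_map, ad = ad_map, rd = rd_map, outlier_fraction = out_map,
       mean_outlier_fraction = if (nmask) sum(out_map) / nmask else 0,
       frame_rejection_fraction = if (n_valid) frame_rej / n_valid else
         frame_rej,
       n_invalid = n_invalid, tensor_evecs = evec)
}
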