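#' Rigid registration of one volume to a reference
#'
#' Estimates the six rigid parameters (three translations in mm, three
#' rotations in radians about the volume centre, x-y-z order) minimizing the
#' mean squared intensity difference between the fixed volume and the moving
#' volume resampled trilinearly under the transform. Optimization is
#' derivative-free (Nelder-Mead) from zero initialization, so the result is
#' deterministic. Same-modality registration makes plain MSE an adequate
#' cost.
#'
#' @param moving,fixed 3D arrays on the same grid.
#' @param voxel_dims Voxel dimensions in mm.
#' @param maxit Optimizer iteration cap.
#' @return A list: `params` (length 6), `residual` (final MSE), `converged`.
#' @export
register_rigid <- function(moving, fixed, voxel_dims = c(1.88, 1.88, 3),
                           maxit = 400) {
  stopifnot(all(dim(moving) == dim(fixed)))
  grid <- rigid_grid(dim(moving), voxel_dims)
  cost <- function(p) mean((fixed - apply_rigid(moving, p, voxel_dims,
                                                grid))^2)
  cost0 <- cost(numeric(6))
  par <- numeric(6)
  val <- cost0
  conv <- TRUE
  # Nelder-Mead with restarts: the simplex collapses long before the
  # optimum on image-matching costs, so re-expanding it from the current
  # point is the standard remedy.
  for (stage in 1:3) {
    fit <- optim(par, cost, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12,
                                parscale = c(1, 1, 1, 0.05, 0.05, 0.05)))
    conv <- fit$convergence == 0
    improved <- fit$value < val - 1e-14
    par <- fit$par
    val <- fit$value
    if (!improved) break
  }
  if (val > cost0) {
    warn("rigid registration did not improve on zero; returning zeros.")
    return(list(params = numeric(6), residual = cost0, converged = FALSE))
  }
  list(params = par, residual = val, converged = conv)
}

#' Estimate the per-frame rigid motion trace of an acquisition
#'
#' Registers every b > 0 frame to the first b = 0 frame and collects the six
#' rigid parameters per frame in acquisition order.
#'
#' @param vol A [dwi_volume()].
#' @param gtab Matching [gradient_table()].
#' @param maxit Optimizer cap per frame.
#' @return A tibble: `frame` (index into the acquisition), `tx`, `ty`, `tz`
#'   (mm), `rx`, `ry`, `rz` (radians), `residual`.
#' @export
estimate_motion_trace <- function(vol, gtab, maxit = 400) {
  b0_idx <- which(gtab$bval == 0)[1]
  fixed <- vol$data[, , , b0_idx]
  dwi_idx <- which(gtab$bval > 0)
  rows <- purrr::map(dwi_idx, function(k) {
    reg <- register_rigid(vol$data[, , , k], fixed, vol$voxel_dims, maxit)
    tibble(frame = k, tx = reg$params[1], ty = reg$params[2],
           tz = reg$params[3], rx = reg$params[4], ry = reg$params[5],
           rz = reg$params[6], residual = reg$residual)
  })
  purrr::list_rbind(rows)
}

#' Scalar head-motion index from a motion trace
#'
#' For each of the six rigid parameters the absolute displacement between
#' adjacent frames is averaged; the index is the sum of the six averages.
#' It is unitless by construction (millimetres and radians are summed), is
#' zero for a static series, and is invariant to a constant offset in any
#' parameter.
#'
#' @param trace A tibble or matrix with columns/6 columns `tx`, `ty`, `tz`,
#'   `rx`, `ry`, `rz`, frames in acquisition order.
#' @return Nonnegative scalar; 0 (with a warning) for a single frame.
#' @examples
#' motion_index(data.frame(tx = c(0, 1, 0, 1, 0), ty = 0, tz = 0,
#'                         rx = 0, ry = 0, rz = 0))  # 1
#' @export
motion_index <- function(trace) {
  cols <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m <- if (is.matrix(trace)) {
    stopifnot(ncol(trace) >= 6)
    trace[, 1:6, drop = FALSE]
  } else {
    as.matrix(as.data.frame(trace)[, cols])
  }
  if (nrow(m) < 2) {
    warn("motion index of a single frame is 0 by convention.")
    return(0)
  }
  sum(colMeans(abs(diff(m))))
}

#' Rigid motion correction by per-frame resampling
#'
#' Resamples every diffusion-weighted frame under its rigid transform so the
#' series is aligned to the b = 0 reference. `params_are = "alignment"`
#' applies the parameters as estimated by [register_rigid()] (which already
#' map the moving frame onto the reference); `params_are = "motion"` treats
#' them as the head motion itself and applies the inverse transform.
#'
#' @param vol A [dwi_volume()].
#' @param gtab Matching [gradient_table()].
#' @param trace Motion-trace tibble (see [estimate_motion_trace()]); rows
#'   must correspond to the b > 0 frames in acquisition order (a `frame`
#'   column, if present, is used to match frames).
#' @param params_are `"alignment"` or `"motion"`.
#' @return A corrected [dwi_volume()].
#' @export
correct_motion <- function(vol, gtab, trace,
                           params_are = c("alignment", "motion")) {
  params_are <- match.arg(params_are)
  dwi_idx <- which(gtab$bval > 0)
  tr <- as.data.frame(trace)
  frames <- if ("frame" %in% names(tr)) tr$frame else dwi_idx
  stopifnot(length(frames) == nrow(tr))
  grid <- rigid_grid(grid_shape(vol), vol$voxel_dims)
  data <- vol$data
  for (i in seq_along(frames)) {
    k <- frames[i]
    p <- as.numeric(tr[i, c("tx", "ty", "tz", "rx", "ry", "rz")])
    if (all(p == 0)) next
    if (params_are == "motion") {
      # exact inverse of x -> R (x - c) + c + t
      R <- euler_rotation(p[4], p[5], p[6])
      data[, , , k] <- apply_rigid_matrix(vol$data[, , , k], t(R),
                                          -drop(t(R) %*% p[1:3]),
                                          vol$voxel_dims, grid)
    } else {
      data[, , , k] <- apply_rigid(vol$data[, , , k], p, vol$voxel_dims,
                                   grid)
    }
  }
  dwi_volume(data, voxel_dims = vol$voxel_dims, affine = vol$affine)
}
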