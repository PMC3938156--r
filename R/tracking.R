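# Sticks at an integer (0-based) voxel with fraction above `thr`,
# sign-resolved toward `prev`. Returns list(dirs = k x 3, dots = k).
voxel_sticks_toward <- function(field, v, prev, thr) {
  i <- v[1] + 1L; j <- v[2] + 1L; k <- v[3] + 1L
  n <- field$n_sticks[i, j, k]
  if (n == 0L) return(NULL)
  fr <- field$fractions[i, j, k, seq_len(n)]
  sel <- which(fr > thr)
  if (!length(sel)) return(NULL)
  dirs <- matrix(field$orientations[i, j, k, sel, ], ncol = 3)
  dots <- drop(dirs %*% prev)
  flip <- dots < 0
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  dots <- abs(dots)
  list(dirs = dirs, dots = dots)
}

#' Interpolate the incoming propagation direction at a continuous position
#'
#' For each of the 8 voxels at the corners of the trilinear cell containing
#' `position`, the stick with volume fraction above the tracking threshold
#' and the smallest turning angle versus `previous_dir` (after resolving the
#' sign of the axial orientation toward it) is selected; the selected
#' directions are blended with the trilinear weights and normalized.
#'
#' @param position Continuous 0-based voxel coordinates (length 3).
#' @param previous_dir Unit previous direction.
#' @param field A `stick_field`.
#' @param config A [run_config()] (uses `fraction_threshold`).
#' @return Unit direction, or `NULL` if no surrounding voxel contributes.
#' @export
interpolate_direction <- function(position, previous_dir, field,
                                  config = run_config()) {
  gs <- field$grid_shape
  base <- floor(position - 0.5)
  fr <- position - 0.5 - base
  acc <- c(0, 0, 0)
  any_w <- FALSE
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    v <- base + c(dx, dy, dz)
    if (any(v < 0) || any(v >= gs)) next
    w <- (if (dx) fr[1] else 1 - fr[1]) *
      (if (dy) fr[2] else 1 - fr[2]) *
      (if (dz) fr[3] else 1 - fr[3])
    if (w <= 0) next
    st <- voxel_sticks_toward(field, v, previous_dir,
                              config$fraction_threshold)
    if (is.null(st)) next
    pick <- which.max(st$dots)       # smallest turning angle
    acc <- acc + w * st$dirs[pick, ]
    any_w <- TRUE
  }
  if (!any_w || vnorm(acc) == 0) return(NULL)
  unit(acc)
}

in_mask <- function(pos, mask, gs) {
  v <- floor(pos)
  if (any(v < 0) || any(v >= gs)) return(FALSE)
  mask[v[1] + 1, v[2] + 1, v[3] + 1] > 0
}

# One half-track from `seed` along initial direction `dir0`.
half_track <- function(seed, dir0, field, mask, config) {
  gs <- field$grid_shape
  pts <- matrix(0, config$max_steps, 3)
  n <- 0L
  pos <- seed
  u <- dir0
  reason <- "max_steps"
  sw <- config$smoothing_weight
  for (s in seq_len(config$max_steps)) {
    w <- interpolate_direction(pos, u, field, config)
    if (is.null(w)) { reason <- "no_direction"; break }
    if (angle_deg(u, w) > config$angle_threshold_deg) {
      reason <- "angle"; break
    }
    nd <- unit(sw * u + (1 - sw) * w)
    pos <- pos + config$step_size_voxels * nd
    if (!in_mask(pos, mask, gs)) { reason <- "out_of_mask"; break }
    n <- n + 1L
    pts[n, ] <- pos
    u <- nd
  }
  list(points = pts[seq_len(n), , drop = FALSE], reason = reason)
}

#' Propagate one streamline from a seed point
#'
#' Tracking starts along the most prominent (highest-fraction) stick of the
#' seed voxel and proceeds bidirectionally; the two half-tracks are
#' concatenated. At each step the new direction blends the previous
#' direction and the incoming interpolated direction with the configured
#' smoothing weights (0.5/0.5 by default), the position advances by the
#' step size in per-axis voxel widths, and propagation stops when the
#' turning angle exceeds the threshold, no direction is available, the
#' position leaves the mask, or the step cap is reached.
#'
#' @param seed Continuous 0-based voxel coordinates of the seed.
#' @param field A `stick_field`.
#' @param mask 3D binary tracking mask.
#' @param config A [run_config()].
#' @param bidirectional Track both along and against the initial stick.
#' @return A list: `points` (n x 3, includes the seed), `seed_point` (row
#'   index of the seed), `termination` (forward half's reason),
#'   `termination_bwd`.
#' @export
propagate <- function(seed, field, mask, config = run_config(),
                      bidirectional = TRUE) {
  gs <- field$grid_shape
  v <- floor(seed)
  if (any(v < 0) || any(v >= gs)) abort("seed outside the grid.")
  i <- v[1] + 1L; j <- v[2] + 1L; k <- v[3] + 1L
  n <- field$n_sticks[i, j, k]
  if (n == 0L) {
    return(list(points = matrix(seed, 1, 3), seed_point = 1L,
                termination = "no_direction", termination_bwd = "no_direction"))
  }
  frs <- field$fractions[i, j, k, seq_len(n)]
  v0 <- field$orientations[i, j, k, which.max(frs), ]
  fwd <- half_track(seed, v0, field, mask, config)
  if (bidirectional) {
    bwd <- half_track(seed, -v0, field, mask, config)
  } else {
    bwd <- list(points = matrix(0, 0, 3), reason = "no_direction")
  }
  pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
               matrix(seed, 1, 3),
               fwd$points)
  list(points = pts, seed_point = nrow(bwd$points) + 1L,
       termination = fwd$reason, termination_bwd = bwd$reason)
}

#' Seed a mask uniformly and track every seed
#'
#' Seed positions are drawn uniformly over the union of the seed-mask voxel
#' volumes (a uniformly chosen mask voxel, then a uniform position inside
#' it) with a fixed seed, so tractograms are reproducible. Streamlines with
#' fewer than 2 points are discarded from the tractogram but counted.
#'
#' @param seed_mask 3D binary seed region (nonempty).
#' @param field A `stick_field`.
#' @param mask 3D binary tracking mask.
#' @param config A [run_config()] (uses `n_seeds`, `rng_seed`).
#' @param seed_mask_name Label recorded in the tractogram.
#' @return A [tractogram()]; its `info` tibble has one row per *retained*
#'   streamline (`seed_index`, `seed_point`, `termination`,
#'   `termination_bwd`), and `attr(, "n_discarded")` counts dropped seeds.
#' @export
seed_and_track <- function(seed_mask, field, mask, config = run_config(),
                           seed_mask_name = "seed") {
  vox <- which(seed_mask > 0, arr.ind = TRUE)
  if (!nrow(vox)) abort("empty seed mask.")
  seeds <- with_local_seed(config$rng_seed, {
    pick <- sample.int(nrow(vox), config$n_seeds, replace = TRUE)
    (vox[pick, , drop = FALSE] - 1L) + matrix(runif(3 * config$n_seeds),
                                              ncol = 3)
  })
  streamlines <- list()
  info <- list()
  n_disc <- 0L
  for (s in seq_len(config$n_seeds)) {
    tr <- propagate(seeds[s, ], field, mask, config)
    if (nrow(tr$points) < 2) {
      n_disc <- n_disc + 1L
      next
    }
    streamlines[[length(streamlines) + 1]] <- tr$points
    info[[length(info) + 1]] <- tibble(
      seed_index = s, seed_point = tr$seed_point,
      termination = tr$termination, termination_bwd = tr$termination_bwd)
  }
  out <- tractogram(streamlines, config = config,
                    seed_mask_name = seed_mask_name,
                    info = if (length(info)) purrr::list_rbind(info) else
                      tibble(seed_index = integer(), seed_point = integer(),
                             termination = character(),
                             termination_bwd = character()))
  attr(out, "grid_shape") <- field$grid_shape
  attr(out, "n_discarded") <- n_disc
  out
}
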