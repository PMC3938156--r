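#' Sort streamlines into seed-to-target pathways
#'
#' A streamline belongs to a target if any of its points falls inside the
#' target mask (point to voxel by floor). A streamline intersecting several
#' targets is assigned to the one reached first along its arc length from
#' the seed point; streamlines reaching no target are discarded (but
#' counted).
#'
#' @param tract A [tractogram()] whose `info` carries `seed_point`.
#' @param targets Named list of 3D binary target masks.
#' @return A tibble with one row per streamline: `streamline`, `target`
#'   (`NA` for discarded), `arc_steps` (steps from seed to first hit).
#' @export
sort_streamlines <- function(tract, targets) {
  stopifnot(length(targets) > 0, !is.null(names(targets)))
  n <- length(tract$streamlines)
  seed_pt <- if (!is.null(tract$info) && nrow(tract$info) == n) {
    tract$info$seed_point
  } else {
    rep(1L, n)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pts <- floor(tract$streamlines[[i]]) + 1L
    best_target <- NA_character_
    best_arc <- Inf
    for (nm in names(targets)) {
      m <- targets[[nm]]
      gs <- dim(m)
      ok <- pts[, 1] >= 1 & pts[, 1] <= gs[1] &
        pts[, 2] >= 1 & pts[, 2] <= gs[2] &
        pts[, 3] >= 1 & pts[, 3] <= gs[3]
      hit <- which(ok)[m[pts[ok, , drop = FALSE]] > 0]
      if (!length(hit)) next
      arc <- min(abs(hit - seed_pt[i]))
      if (arc < best_arc) {
        best_arc <- arc
        best_target <- nm
      }
    }
    rows[[i]] <- tibble(streamline = i, target = best_target,
                        arc_steps = if (is.finite(best_arc)) best_arc else
                          NA_real_)
  }
  purrr::list_rbind(rows)
}

#' Streamline visitation map
#'
#' Counts, per voxel, the number of *distinct* streamlines with at least one
#' point in it (multiple points of one streamline in one voxel count once).
#'
#' @param streamlines List of n x 3 point matrices (voxel coordinates).
#' @param grid_shape Integer length-3 grid size.
#' @return Integer 3D array of visit counts.
#' @export
visitation_map <- function(streamlines, grid_shape) {
  vm <- array(0L, grid_shape)
  for (m in streamlines) {
    v <- floor(m)
    ok <- v[, 1] >= 0 & v[, 1] < grid_shape[1] &
      v[, 2] >= 0 & v[, 2] < grid_shape[2] &
      v[, 3] >= 0 & v[, 3] < grid_shape[3]
    v <- unique(v[ok, , drop = FALSE]) + 1L
    if (nrow(v)) vm[v] <- vm[v] + 1L
  }
  vm
}

#' Per-pathway metrics: SC, SV and mean FA/AD/RD over pathway voxels
#'
#' Pathway voxels are those visited by strictly more than
#' `visitation_threshold` streamlines (default "more than 5 visits"). SC is
#' the streamline count of the subset; SV the summed volume of pathway
#' voxels; FA/AD/RD the unweighted means of the scalar maps over pathway
#' voxels (`NA` when the voxel set is empty).
#'
#' @param streamlines List of point matrices belonging to one pathway.
#' @param fa_map,ad_map,rd_map Scalar 3D maps co-registered with the grid.
#' @param voxel_dims Voxel dimensions (mm).
#' @param visitation_threshold Strict lower bound on visits.
#' @param pathway Pathway name for the output row.
#' @return One-row tibble: `pathway`, `SC`, `SV`, `FA`, `AD`, `RD`,
#'   `n_voxels`; the voxel index set is attached as `attr(, "voxels")`.
#' @export
pathway_metrics <- function(streamlines, fa_map, ad_map, rd_map,
                            voxel_dims = c(1.88, 1.88, 3),
                            visitation_threshold = 5L,
                            pathway = "pathway") {
  gs <- dim(fa_map)
  vm <- visitation_map(streamlines, gs)
  sel <- which(vm > visitation_threshold)
  sc <- length(streamlines)
  sv <- length(sel) * voxel_volume(voxel_dims)
  out <- tibble(pathway = pathway,
                SC = sc,
                SV = sv,
                FA = if (length(sel)) mean(fa_map[sel]) else NA_real_,
                AD = if (length(sel)) mean(ad_map[sel]) else NA_real_,
                RD = if (length(sel)) mean(rd_map[sel]) else NA_real_,
                n_voxels = length(sel))
  attr(out, "voxels") <- sel
  out
}

#' Flag a single subject's value against a reference group
#'
#' Two single-subject criteria: `"three_se"` flags values below
#' `mean(ref) - 3 * sd(ref) / sqrt(n(ref))` (three standard errors of the
#' reference group); `"lower_decile"` flags values below the empirical 10th
#' percentile of the reference (linear interpolation). Both comparisons are
#' strict (`<`).
#'
#' @param value Scalar to test.
#' @param reference_values Reference group values (length >= 2).
#' @param criterion `"three_se"` or `"lower_decile"`.
#' @return Logical.
#' @examples
#' flag_single_subject(0.23, rnorm(14, 0.27, 0.03), "three_se")
#' @export
flag_single_subject <- function(value,
                                reference_values,
                                criterion = c("three_se", "lower_decile")) {
  criterion <- match.arg(criterion)
  ref <- reference_values[is.finite(reference_values)]
  if (length(ref) < 2) abort("reference group needs >= 2 values.")
  thr <- switch(criterion,
                three_se = mean(ref) - 3 * sd(ref) / sqrt(length(ref)),
                lower_decile = unname(quantile(ref, 0.10, type = 7)))
  isTRUE(value < thr)
}
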