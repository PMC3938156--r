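#' Pipeline run configuration
#'
#' Bundles every tunable the tracking pipeline reads. The defaults are the
#' published operating point of the method: 0.2-voxel steps, a 60 degree
#' turning-angle threshold, sticks eligible for tracking above a volume
#' fraction of 0.15, pathway voxels requiring more than 5 streamline visits,
#' 2000 seed points, and equal (0.5/0.5) smoothing of the previous and
#' incoming propagation directions.
#'
#' @param step_size_voxels Step length in per-axis voxel widths.
#' @param angle_threshold_deg Maximum turning angle between consecutive
#'   directions before a streamline terminates.
#' @param fraction_threshold Minimum stick volume fraction eligible for
#'   direction interpolation during tracking.
#' @param visitation_threshold Pathway voxels must receive strictly more
#'   visits than this.
#' @param n_seeds Number of seed points distributed over the seed mask.
#' @param smoothing_weight Weight of the previous direction when blending
#'   with the incoming interpolated direction.
#' @param rng_seed Integer seed controlling every stochastic step.
#' @param max_steps Hard cap on steps per half-track.
#' @param window_layout Local window geometry for the multi-fiber fit:
#'   `"eleven"` (centre + 6 face neighbours + 4 in-slice diagonals),
#'   `"face"` (7) or `"cube"` (27).
#' @param min_stick_fraction Sticks below this fraction are pruned at fit
#'   time (distinct from `fraction_threshold`, which tracking applies).
#' @param reject_threshold Outlier rejection threshold for the robust tensor
#'   fit, in robust-sigma units.
#' @return A list of class `dentract_config`.
#' @export
run_config <- function(step_size_voxels = 0.2,
                       angle_threshold_deg = 60,
                       fraction_threshold = 0.15,
                       visitation_threshold = 5L,
                       n_seeds = 2000L,
                       smoothing_weight = 0.5,
                       rng_seed = 1L,
                       max_steps = 2000L,
                       window_layout = c("eleven", "face", "cube"),
                       min_stick_fraction = 0.05,
                       reject_threshold = 3.0) {
  window_layout <- match.arg(window_layout)
  cfg <- list(step_size_voxels = step_size_voxels,
              angle_threshold_deg = angle_threshold_deg,
              fraction_threshold = fraction_threshold,
              visitation_threshold = as.integer(visitation_threshold),
              n_seeds = as.integer(n_seeds),
              smoothing_weight = smoothing_weight,
              rng_seed = as.integer(rng_seed),
              max_steps = as.integer(max_steps),
              window_layout = window_layout,
              min_stick_fraction = min_stick_fraction,
              reject_threshold = reject_threshold)
  num <- vapply(cfg[c("step_size_voxels", "angle_threshold_deg",
                      "fraction_threshold", "visitation_threshold",
                      "n_seeds", "smoothing_weight")], as.numeric, 1)
  if (any(num <= 0)) abort("config values must be positive.")
  structure(cfg, class = "dentract_config")
}

#' Read a flat key=value config file, applying overrides
#'
#' Lines look like `n_seeds = 500`; `#` starts a comment. Values in
#' `overrides` (e.g. from CLI flags) take precedence over the file, which
#' takes precedence over the package defaults.
#'
#' @param path Path to the config file, or `NULL` for defaults only.
#' @param overrides Named list of values overriding the file.
#' @return A [run_config()].
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      vals[[key]] <- if (is.na(num)) val else num
    }
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) abort(paste("unknown config key(s):",
                                   paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}

#' @export
format.dentract_config <- function(x, ...) {
  paste0(names(x), " = ", vapply(x, function(v) paste(format(v), collapse = ","),
                                 ""), collapse = "\n")
}

#' @export
print.dentract_config <- function(x, ...) {
  cat("<dentract_config>\n", format(x), "\n", sep = "")
  invisible(x)
}
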