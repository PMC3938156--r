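#' Run the full single-subject pipeline
#'
#' Executes, in order: motion quality control (per-frame rigid registration
#' to the b = 0 frame and the scalar motion index), robust tensor fitting
#' with FA/AD/RD and outlier-fraction maps, the multi-fiber ICA +
#' ball-and-stick fit, seeding and deterministic tracking, streamline
#' sorting into the named target pathways, and per-pathway metrics. A stage
#' failure aborts downstream stages and is recorded in the manifest.
#'
#' @param dwi A [dwi_volume()].
#' @param gtab Matching [gradient_table()].
#' @param seed_mask 3D binary seed region.
#' @param target_masks Named list of 3D binary target masks.
#' @param mask 3D binary analysis/tracking mask (e.g. white matter).
#' @param config A [run_config()].
#' @param motion `"estimate"` to register every diffusion-weighted frame,
#'   `"none"` to skip (index `NA`), or an externally supplied motion-trace
#'   tibble (see [estimate_motion_trace()]).
#' @param motion_maxit Optimizer cap per registration.
#' @param correct Apply rigid motion correction (frame resampling) before
#'   fitting, whenever a motion trace is available.
#' @param params_are How a *supplied* trace is interpreted by
#'   [correct_motion()]: `"alignment"` (registration output) or `"motion"`
#'   (the head motion itself, e.g. a simulation's injected trace).
#' @return A list of class `dentract_subject`: `metrics` (one row per
#'   pathway, plus subject-level columns `motion_index`,
#'   `mean_outlier_fraction`, `no_stick_density`, `n_streamlines`,
#'   `n_discarded`), `maps`, `field`, `tractogram`, `sorted`, `manifest`.
#' @export
run_subject <- function(dwi, gtab, seed_mask, target_masks, mask,
                        config = run_config(), motion = "estimate",
                        motion_maxit = 200, correct = TRUE,
                        params_are = "alignment") {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (is.null(names(target_masks)) || any(!nzchar(names(target_masks)))) {
    abort("every target mask must be named.")
  }
  for (nm in names(target_masks)) {
    if (is.null(target_masks[[nm]])) abort(sprintf("missing target mask '%s'.", nm))
  }
  manifest <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- expr
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = name, status = "ok",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  trace <- NULL
  m_index <- NA_real_
  if (is.data.frame(motion)) {
    trace <- motion
    m_index <- stage("motion", motion_index(trace))
  } else if (identical(motion, "estimate")) {
    trace <- stage("motion", estimate_motion_trace(dwi, gtab,
                                                   maxit = motion_maxit))
    m_index <- motion_index(trace)
    params_are <- "alignment"
  }
  if (correct && !is.null(trace)) {
    dwi <- stage("motion_correction",
                 correct_motion(dwi, gtab, trace, params_are))
  }
  maps <- stage("tensor", compute_scalar_maps(dwi, gtab, mask,
                                              config$reject_threshold))
  # whole-frame dropouts corrupt the window decomposition, which (unlike the
  # robust tensor fit) has no per-measurement outlier model: drop them
  bad_frames <- stage("frame_qc", detect_outlier_frames(maps))
  if (length(bad_frames) && nrow(gtab) - length(bad_frames) >= 8) {
    keep <- setdiff(seq_len(nrow(gtab)), bad_frames)
    dwi_fit <- dwi_volume(dwi$data[, , , keep, drop = FALSE],
                          voxel_dims = dwi$voxel_dims, affine = dwi$affine)
    gtab_fit <- gradient_table(gtab$bval[keep],
                               cbind(gtab$gx, gtab$gy, gtab$gz)[keep, ])
  } else {
    dwi_fit <- dwi
    gtab_fit <- gtab
  }
  field <- stage("icabsm", fit_stick_field(dwi_fit, mask, gtab_fit, config))
  tract <- stage("tracking", seed_and_track(seed_mask, field, mask, config))
  sorted <- stage("sorting", sort_streamlines(tract, target_masks))
  metrics <- stage("metrics", {
    purrr::map(names(target_masks), function(nm) {
      idx <- sorted$streamline[!is.na(sorted$target) & sorted$target == nm]
      pathway_metrics(tract$streamlines[idx], maps$fa, maps$ad, maps$rd,
                      voxel_dims = dwi$voxel_dims,
                      visitation_threshold = config$visitation_threshold,
                      pathway = nm)
    }) |> purrr::list_rbind()
  })
  metrics <- metrics |>
    mutate(motion_index = m_index,
           mean_outlier_fraction = maps$mean_outlier_fraction,
           n_outlier_frames = length(bad_frames),
           no_stick_density = field$no_stick_density,
           n_streamlines = length(tract),
           n_discarded = sum(is.na(sorted$target)))
  structure(list(metrics = metrics, maps = maps, field = field,
                 tractogram = tract, sorted = sorted, motion_trace = trace,
                 manifest = purrr::list_rbind(manifest)),
            class = "dentract_subject")
}

#' Run a whole cohort and its group statistics
#'
#' Applies [run_subject()] to every subject of a simulated (or assembled)
#' cohort, joins the per-pathway metrics with the covariate table, and runs
#' the group statistics: covariate-adjusted group tests per metric,
#' single-subject flag percentages under both criteria, and per-group
#' empirical CDFs. Subject failures are tolerated (listwise exclusion) and
#' recorded.
#'
#' @param cohort A list as returned by [simulate_cohort()]: `subjects`
#'   (each with `dwi` and `truth` carrying `seed_mask`, `target_masks`,
#'   `mask`) and `covariates` (tibble with `subject`, `group`, `age`).
#' @param config A [run_config()].
#' @param motion Passed to [run_subject()]; the default `"estimate"`
#'   registers every frame, `"truth"` uses the injected motion trace.
#' @param metrics Metric columns to test.
#' @return A list of class `dentract_cohort`: `records` (long per-subject
#'   per-pathway tibble), `group_tests` (named list of
#'   [glm_group_test()] results), `flags`, `cdfs`, `subject_results`,
#'   `failures`, `covariates`.
#' @export
run_cohort <- function(cohort, config = run_config(), motion = "estimate",
                       metrics = c("FA", "AD", "RD", "SC", "SV")) {
  stopifnot(is.list(cohort$subjects), is.data.frame(cohort$covariates))
  results <- list()
  failures <- character()
  for (nm in names(cohort$subjects)) {
    sub <- cohort$subjects[[nm]]
    mot <- if (identical(motion, "truth")) {
      tr <- sub$truth$motion_trace
      tibble(frame = seq_len(nrow(tr)), tx = tr[, 1], ty = tr[, 2],
             tz = tr[, 3], rx = tr[, 4], ry = tr[, 5], rz = tr[, 6])
    } else motion
    gtab <- cohort$gtab %||% default_gradient_table()
    res <- tryCatch(
      run_subject(sub$dwi, gtab,
                  sub$truth$seed_mask, sub$truth$target_masks,
                  mask = sub$truth$mask, config = config, motion = mot,
                  params_are = if (identical(motion, "truth")) "motion" else
                    "alignment"),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, nm)
      warn(sprintf("subject %s failed: %s", nm, conditionMessage(res)))
    } else {
      results[[nm]] <- res
    }
  }
  records <- purrr::imap(results, function(r, nm)
    mutate(r$metrics, subject = nm, .before = 1)) |>
    purrr::list_rbind() |>
    left_join(cohort$covariates, by = "subject") |>
    dplyr::rename(motion = "motion_index")
  group_tests <- purrr::map(setNames(metrics, metrics), function(m)
    tryCatch(glm_group_test(records, m), error = function(e) NULL))
  flags <- flag_table(records, metrics)
  cdfs <- records |>
    tidyr::pivot_longer(all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    filter(is.finite(.data$value)) |>
    group_by(.data$group, .data$pathway, .data$metric) |>
    dplyr::reframe(empirical_cdf(.data$value))
  structure(list(records = records, group_tests = group_tests,
                 flags = flags, cdfs = cdfs, subject_results = results,
                 failures = failures, covariates = cohort$covariates),
            class = "dentract_cohort")
}

#' @export
print.dentract_cohort <- function(x, ...) {
  cat(sprintf("<dentract_cohort> %d subjects analysed (%d failed)\n",
              length(x$subject_results), length(x$failures)))
  for (m in names(x$group_tests)) {
    gt <- x$group_tests[[m]]
    if (is.null(gt)) next
    sig <- gt$table |> filter(.data$p_value < 0.05)
    cat(sprintf("  %s: %d/%d pathways with p < 0.05\n", m, nrow(sig),
                nrow(gt$table)))
  }
  invisible(x)
}
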