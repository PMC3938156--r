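#' @importFrom ggplot2 ggplot aes geom_step geom_point geom_line geom_path
#'   geom_errorbar geom_col facet_wrap facet_grid labs theme_minimal autoplot
NULL

#' Re-exported generics
#'
#' `tidy()` and `glance()` from broom and `autoplot()` from ggplot2, so the
#' package's methods work without attaching those packages.
#' @name reexports
#' @keywords internal
#' @importFrom broom tidy
#' @export
broom::tidy

#' @rdname reexports
#' @importFrom broom glance
#' @export
broom::glance

#' @rdname reexports
#' @export
ggplot2::autoplot

#' Plot per-group empirical CDFs of a pathway metric
#'
#' @param records Long metric tibble (see [glm_group_test()]).
#' @param metric Metric column to plot.
#' @return A ggplot: one panel per pathway, one step curve per group.
#' @export
plot_cdf <- function(records, metric = "FA") {
  df <- records |>
    dplyr::rename(value = all_of(metric)) |>
    filter(is.finite(.data$value)) |>
    group_by(.data$group, .data$pathway) |>
    dplyr::reframe(empirical_cdf(.data$value))
  ggplot(df, aes(x = .data$value, y = .data$cdf, colour = .data$group)) +
    geom_step() +
    facet_wrap(~pathway, scales = "free_x") +
    labs(x = metric, y = sprintf("P(%s ≤ X)", metric)) +
    theme_minimal()
}

#' Plot a motion trace
#'
#' @param trace Motion trace tibble (see [estimate_motion_trace()]).
#' @return A ggplot of the six rigid parameters over frames.
#' @export
plot_motion_trace <- function(trace) {
  df <- trace |>
    tidyr::pivot_longer(all_of(c("tx", "ty", "tz", "rx", "ry", "rz")),
                        names_to = "parameter", values_to = "value")
  ggplot(df, aes(x = .data$frame, y = .data$value)) +
    geom_line() +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = "frame", y = "displacement (mm or rad)") +
    theme_minimal()
}

#' Plot adjusted group effects of a group test
#'
#' @param object A [glm_group_test()] result.
#' @param ... Unused.
#' @return A ggplot of per-pathway group means with SD bars.
#' @export
autoplot.dentract_group_test <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(all_of(c("mean_A", "mean_B")), names_to = "group",
                        values_to = "mean") |>
    mutate(sd = ifelse(.data$group == "mean_A", .data$sd_A, .data$sd_B),
           group = sub("mean_", "", .data$group))
  ggplot(df, aes(x = .data$pathway, y = .data$mean, fill = .data$group)) +
    geom_col(position = "dodge") +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd),
                  position = "dodge") +
    labs(y = object$metric) +
    theme_minimal()
}

#' Plot a tractogram as a 2D projection
#'
#' @param object A [tractogram()].
#' @param plane Projection plane: `"xy"`, `"xz"` or `"yz"`.
#' @param ... Unused.
#' @return A ggplot with one path per streamline.
#' @export
autoplot.tractogram <- function(object, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  df <- tidy(object)
  ggplot(df, aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                 group = .data$streamline)) +
    geom_path(alpha = 0.3) +
    labs(x = paste(ax[1], "(voxels)"), y = paste(ax[2], "(voxels)")) +
    theme_minimal()
}
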