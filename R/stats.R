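utils::globalVariables(c("value"))

pathway_levels <- c("L_DDN", "L_VDN", "R_DDN", "R_VDN")

# Drop covariates with (near-)zero variance, with a warning.
usable_covariates <- function(df, covariates) {
  keep <- character()
  for (cv in covariates) {
    x <- df[[cv]]
    if (is.null(x) || !is.finite(var(x)) || var(x) < 1e-12) {
      warn(sprintf("covariate '%s' is constant or missing; dropped.", cv))
    } else {
      keep <- c(keep, cv)
    }
  }
  keep
}

#' Group comparison of one pathway metric with covariate adjustment
#'
#' For each pathway, fits the linear model `value ~ group + age + motion`
#' and reports the group-effect F-test (equivalent to the squared t of the
#' group coefficient for two groups), the adjusted effect estimate, and the
#' raw per-group mean and SD. A multivariate omnibus test (Wilks' lambda
#' across the four pathways) is reported alongside.
#'
#' @param records Long tibble with columns `subject`, `group` (two levels),
#'   `age`, `motion`, `pathway`, and the metric columns (`FA`, `AD`, `RD`,
#'   `SC`, `SV`).
#' @param metric Name of the metric column to test.
#' @param covariates Covariate column names (default age and motion).
#' @param omnibus Also fit the Wilks' lambda omnibus (skippable in large
#'   simulation loops).
#' @param age_split Optional age (years): run the test separately within the
#'   `<= age_split` and `> age_split` strata and bind the results with an
#'   `age_group` column (the age-subgroup analysis).
#' @return An object of class `dentract_group_test`; see
#'   [tidy.dentract_group_test()] and [glance.dentract_group_test()].
#' @export
glm_group_test <- function(records, metric,
                           covariates = c("age", "motion"),
                           omnibus = TRUE, age_split = NULL) {
  if (!is.null(age_split)) {
    stratum <- function(df, label) {
      res <- tryCatch(glm_group_test(df, metric, covariates,
                                     omnibus = FALSE),
                      error = function(e) {
                        warn(sprintf("age stratum %s skipped: %s", label,
                                     conditionMessage(e)))
                        NULL
                      })
      if (is.null(res)) NULL else mutate(res$table, age_group = label)
    }
    all_ages <- glm_group_test(records, metric, covariates, omnibus)
    all_ages$table <- bind_rows(
      mutate(all_ages$table, age_group = "all"),
      stratum(filter(records, .data$age <= age_split),
              sprintf("<=%g", age_split)),
      stratum(filter(records, .data$age > age_split),
              sprintf(">%g", age_split)))
    return(all_ages)
  }
  stopifnot(metric %in% names(records))
  groups <- sort(unique(records$group))
  if (length(groups) != 2) abort("exactly two groups required.")
  tab <- records |>
    dplyr::rename(value = all_of(metric)) |>
    filter(is.finite(.data$value))
  counts <- tab |> dplyr::distinct(.data$subject, .data$group) |>
    dplyr::count(.data$group)
  if (any(counts$n < 3)) abort("need >= 3 subjects per group.")
  cvs <- usable_covariates(tab, covariates)
  res <- purrr::map(split(tab, tab$pathway), function(df) {
    df$group <- factor(df$group, levels = groups)
    form <- stats::reformulate(c("group", cvs), response = "value")
    fit <- lm(form, data = df)
    # covariate-adjusted (partial) F test of the group term
    a <- stats::drop1(fit, scope = ~group, test = "F")
    p <- a["group", "Pr(>F)"]
    est <- coef(fit)[[paste0("group", groups[2])]]
    tibble(pathway = df$pathway[1],
           estimate = est,
           statistic = a["group", "F value"],
           p_value = p,
           mean_A = mean(df$value[df$group == groups[1]]),
           sd_A = sd(df$value[df$group == groups[1]]),
           mean_B = mean(df$value[df$group == groups[2]]),
           sd_B = sd(df$value[df$group == groups[2]]),
           n_A = sum(df$group == groups[1]),
           n_B = sum(df$group == groups[2]))
  }) |> purrr::list_rbind()
  # Wilks' lambda omnibus across pathways (complete cases only)
  wilks <- NULL
  wide <- if (omnibus) {
    tab |>
      select(all_of(c("subject", "group", cvs, "pathway", "value"))) |>
      tidyr::pivot_wider(names_from = "pathway", values_from = "value") |>
      tidyr::drop_na()
  } else {
    tibble()
  }
  pws <- intersect(pathway_levels, names(wide))
  if (length(pws) >= 2 && nrow(wide) > length(pws) + length(cvs) + 2) {
    Y <- as.matrix(wide[, pws])
    wide$group <- factor(wide$group, levels = groups)
    form <- stats::reformulate(c("group", cvs), response = "Y")
    mv <- stats::manova(form, data = wide)
    sm <- tryCatch(summary(mv, test = "Wilks")$stats, error = function(e) NULL)
    if (!is.null(sm) && "group" %in% rownames(sm)) {
      wilks <- tibble(statistic = sm["group", "Wilks"],
                      approx_F = sm["group", "approx F"],
                      p_value = sm["group", "Pr(>F)"])
    }
  }
  structure(list(table = res, wilks = wilks, metric = metric,
                 groups = groups, covariates = cvs),
            class = "dentract_group_test")
}

#' @export
print.dentract_group_test <- function(x, ...) {
  cat(sprintf("<group test> metric %s, groups %s vs %s, covariates: %s\n",
              x$metric, x$groups[1], x$groups[2],
              paste(x$covariates, collapse = ", ")))
  print(x$table)
  invisible(x)
}

#' Tidy a group-test result
#'
#' One row per pathway with the adjusted group effect, F statistic, p-value,
#' raw per-group summaries, and a Benjamini-Hochberg adjusted p-value column
#' (`p_adj_bh`, an extension beyond the primary per-pathway reporting).
#'
#' @param x A `dentract_group_test`.
#' @param ... Unused.
#' @export
tidy.dentract_group_test <- function(x, ...) {
  x$table |> mutate(p_adj_bh = stats::p.adjust(.data$p_value, "BH"))
}

#' Omnibus (Wilks' lambda) summary of a group test
#' @param x A `dentract_group_test`.
#' @param ... Unused.
#' @export
glance.dentract_group_test <- function(x, ...) {
  x$wilks %||% tibble(statistic = NA_real_, approx_F = NA_real_,
                      p_value = NA_real_)
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlates the residuals of `x` and `y` after regressing each on the
#' covariates; the p-value uses a t distribution with `n - 2 - k` degrees
#' of freedom (k covariates; n - 4 with the default age + motion pair).
#'
#' @param data Data frame with one row per subject.
#' @param x,y Column names to correlate.
#' @param covariates Covariate column names.
#' @return One-row tibble: `r`, `statistic`, `p_value`, `df`, `n`.
#' @export
partial_correlation <- function(data, x, y,
                                covariates = c("age", "motion")) {
  df <- data[stats::complete.cases(data[, c(x, y, covariates)]), ]
  n <- nrow(df)
  if (n < length(covariates) + 3) abort("need >= 5 complete records.")
  rx <- resid(lm(stats::reformulate(covariates, response = x), data = df))
  ry <- resid(lm(stats::reformulate(covariates, response = y), data = df))
  if (sd(rx) < 1e-14 || sd(ry) < 1e-14) {
    warn("zero-variance residuals; correlation undefined.")
    return(tibble(r = NA_real_, statistic = NA_real_, p_value = NA_real_,
                  df = n - 2 - length(covariates), n = n))
  }
  r <- stats::cor(rx, ry)
  dof <- n - 2 - length(covariates)
  tval <- r * sqrt(dof / max(1 - r^2, 1e-15))
  tibble(r = r, statistic = tval,
         p_value = 2 * pt(-abs(tval), dof), df = dof, n = n)
}

#' Empirical cumulative distribution function
#'
#' P(parameter <= X) at each observed value (steps of 1/n on the sorted
#' sample), the form used to compare per-group pathway metric
#' distributions.
#'
#' @param values Nonempty numeric vector.
#' @return Tibble with columns `value` and `cdf`, sorted by value.
#' @export
empirical_cdf <- function(values) {
  v <- sort(values[is.finite(values)])
  if (!length(v)) abort("no finite values.")
  tibble(value = v, cdf = seq_along(v) / length(v))
}

#' Percentage of test-group subjects flagged per pathway and metric
#'
#' Applies [flag_single_subject()] under both single-subject criteria to
#' every test-group subject, per pathway and metric, and reports the
#' percentage flagged (rounded to whole percent). With
#' `leave_one_out = TRUE` the test group is scored against its own group,
#' excluding each subject from their reference (a calibration mode).
#'
#' @param records Long metric tibble (see [glm_group_test()]).
#' @param metrics Metric columns to scan.
#' @param reference_group,test_group Group labels.
#' @param criteria Subset of `c("three_se", "lower_decile")`.
#' @param leave_one_out Score the reference group against itself.
#' @return Tibble: `pathway`, `metric`, `criterion`, `percent`,
#'   `n_flagged`, `n_tested`.
#' @export
flag_table <- function(records, metrics = c("FA", "AD", "RD", "SC", "SV"),
                       reference_group = "A", test_group = "B",
                       criteria = c("three_se", "lower_decile"),
                       leave_one_out = FALSE) {
  metrics <- intersect(metrics, names(records))
  rows <- list()
  for (pw in unique(records$pathway)) {
    sub <- filter(records, .data$pathway == pw)
    for (met in metrics) {
      ref <- sub[[met]][sub$group == reference_group]
      tst_rows <- if (leave_one_out) which(sub$group == reference_group) else
        which(sub$group == test_group)
      tst_rows <- tst_rows[is.finite(sub[[met]][tst_rows])]
      for (cr in criteria) {
        flags <- vapply(seq_along(tst_rows), function(i) {
          idx <- tst_rows[i]
          ref_i <- if (leave_one_out) {
            sub[[met]][setdiff(which(sub$group == reference_group), idx)]
          } else ref
          ref_i <- ref_i[is.finite(ref_i)]
          if (length(ref_i) < 2) return(NA)
          flag_single_subject(sub[[met]][idx], ref_i, cr)
        }, logical(1))
        flags <- flags[!is.na(flags)]
        rows[[length(rows) + 1]] <- tibble(
          pathway = pw, metric = met, criterion = cr,
          percent = if (length(flags)) round(100 * mean(flags)) else
            NA_real_,
          n_flagged = sum(flags), n_tested = length(flags))
      }
    }
  }
  purrr::list_rbind(rows)
}

#' Within-group ordinary least-squares regression on age
#'
#' @param data One row per subject; must contain `age` and the response.
#' @param response Response column name.
#' @return One-row tibble: `r_squared`, `p_value` (slope test), `slope`,
#'   `intercept`, `n`.
#' @export
age_regression <- function(data, response) {
  df <- data[stats::complete.cases(data[, c("age", response)]), ]
  if (nrow(df) < 3) abort("need >= 3 records.")
  if (var(df$age) < 1e-12) {
    warn("age is constant; regression undefined.")
    return(tibble(r_squared = NA_real_, p_value = NA_real_,
                  slope = NA_real_, intercept = NA_real_, n = nrow(df)))
  }
  fit <- lm(stats::reformulate("age", response = response), data = df)
  sm <- summary(fit)
  tibble(r_squared = sm$r.squared,
         p_value = sm$coefficients["age", "Pr(>|t|)"],
         slope = coef(fit)[["age"]],
         intercept = coef(fit)[["(Intercept)"]],
         n = nrow(df))
}

#' Simulate per-subject pathway metric records (no imaging)
#'
#' A fast statistics-level cohort generator for calibration studies: per
#' subject it draws age and motion from the group's covariate model, then
#' per pathway draws the metric as
#' `baseline + age_slope * age + motion_slope * motion + noise`, with group
#' B's designated pathway shifted down by `effect_sd` pooled SDs. With
#' `effect_sd = 0` the groups are exchangeable (a null cohort).
#'
#' @param n_per_group Length-2 group sizes (default `c(14, 15)`).
#' @param metric Metric column name to fill.
#' @param baseline,sd Metric mean and SD (defaults mirror a pathway FA of
#'   0.27 +/- 0.03).
#' @param effect_sd Group-B shift on `degraded_pathway`, in SD units.
#' @param degraded_pathway Pathway receiving the shift (`"all"` shifts all).
#' @param age_range Uniform age range (years).
#' @param motion_mean,motion_sd Per-group motion-index normal parameters.
#' @param age_slope,motion_slope Covariate effects on the metric.
#' @param rng_seed Seed; `NULL` draws from the current RNG stream (the right
#'   choice inside long simulation loops, where one seeded stream gives
#'   independent cohorts).
#' @return Long tibble: `subject`, `group`, `age`, `motion`, `pathway`,
#'   and the metric column.
#' @export
simulate_metric_records <- function(n_per_group = c(14, 15),
                                    metric = "FA",
                                    baseline = 0.27, sd = 0.03,
                                    effect_sd = 0,
                                    degraded_pathway = "R_VDN",
                                    age_range = c(3.6, 14.0),
                                    motion_mean = c(2.00, 1.12),
                                    motion_sd = c(0.67, 0.63),
                                    age_slope = 0.002,
                                    motion_slope = -0.005,
                                    rng_seed = 1) {
  n_tot <- sum(n_per_group)
  grp <- rep(c("A", "B"), n_per_group)
  gen <- function() {
    age <- runif(n_tot, age_range[1], age_range[2])
    motion <- pmax(0, rnorm(n_tot,
                            ifelse(grp == "A", motion_mean[1], motion_mean[2]),
                            ifelse(grp == "A", motion_sd[1], motion_sd[2])))
    rows <- purrr::map(seq_len(n_tot), function(i) {
      val <- baseline + age_slope * age[i] + motion_slope * motion[i] +
        rnorm(4, sd = sd)
      shift <- if (grp[i] == "B") {
        ifelse(pathway_levels == degraded_pathway | degraded_pathway == "all",
               -effect_sd * sd, 0)
      } else 0
      out <- tibble(subject = sprintf("S%02d", i), group = grp[i],
                    age = age[i], motion = motion[i],
                    pathway = pathway_levels)
      out[[metric]] <- val + shift
      out
    })
    purrr::list_rbind(rows)
  }
  if (is.null(rng_seed)) gen() else with_local_seed(rng_seed, gen())
}
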