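test_that("identical groups give null effects and p near 1", {
  rec <- simulate_metric_records(n_per_group = c(14, 14), effect_sd = 0,
                                 rng_seed = 9)
  rec$FA[rec$group == "B"] <- rec$FA[rec$group == "A"]
  rec$age[rec$group == "B"] <- rec$age[rec$group == "A"]
  rec$motion[rec$group == "B"] <- rec$motion[rec$group == "A"]
  gt <- suppressWarnings(glm_group_test(rec, "FA"))
  expect_true(all(gt$table$p_value > 1 - 1e-6))
  expect_true(all(abs(gt$table$estimate) < 1e-12))
  td <- tidy(gt)
  expect_true(all(c("pathway", "estimate", "p_value", "p_adj_bh") %in%
                    names(td)))
  expect_s3_class(glance(gt), "tbl_df")
})

test_that("constant covariates are dropped with a warning, matching the plain test", {
  rec <- simulate_metric_records(rng_seed = 3)
  rec$motion <- 1.5
  expect_warning(gt <- glm_group_test(rec, "FA"), "constant")
  # oracle: two-sample comparison adjusted only for age
  sub <- rec[rec$pathway == "R_VDN", ]
  fit <- lm(FA ~ group + age, data = sub)
  p_oracle <- stats::drop1(fit, scope = ~group, test = "F")["group", "Pr(>F)"]
  expect_equal(gt$table$p_value[gt$table$pathway == "R_VDN"], p_oracle,
               tolerance = 1e-12)
  # with no covariates at all, the group F equals the squared t statistic
  rec2 <- simulate_metric_records(rng_seed = 4)
  rec2$age <- 5; rec2$motion <- 1
  gt2 <- suppressWarnings(glm_group_test(rec2, "FA"))
  sub2 <- rec2[rec2$pathway == "L_DDN", ]
  tt <- stats::t.test(FA ~ group, data = sub2, var.equal = TRUE)
  expect_equal(gt2$table$statistic[gt2$table$pathway == "L_DDN"],
               unname(tt$statistic)^2, tolerance = 1e-8)
})

test_that("group tests are calibrated under the null and powered at 1.5 SD", {
  set.seed(202)
  ps <- replicate(1000, {
    rec <- simulate_metric_records(effect_sd = 0, rng_seed = NULL)
    suppressWarnings(glm_group_test(rec, "FA",
                                    omnibus = FALSE))$table$p_value[4]
  })
  expect_gte(mean(ps < 0.05), 0.03)
  expect_lte(mean(ps < 0.05), 0.07)
  # p-values uniform under the null
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  pw <- replicate(200, {
    rec <- simulate_metric_records(effect_sd = 1.5, rng_seed = NULL)
    suppressWarnings(glm_group_test(rec, "FA",
                                    omnibus = FALSE))$table$p_value[4] < 0.05
  })
  expect_gte(mean(pw), 0.8)
})

test_that("age-stratified group tests bind strata and skip thin ones", {
  rec <- simulate_metric_records(n_per_group = c(20, 20), effect_sd = 1,
                                 rng_seed = 8)
  gt <- suppressWarnings(glm_group_test(rec, "FA", age_split = 7))
  expect_setequal(unique(gt$table$age_group), c("all", "<=7", ">7"))
  expect_equal(nrow(gt$table), 12)
  # within-stratum result matches a direct call on the subset
  young <- suppressWarnings(
    glm_group_test(dplyr::filter(rec, age <= 7), "FA", omnibus = FALSE))
  expect_equal(gt$table$p_value[gt$table$age_group == "<=7"],
               young$table$p_value, tolerance = 1e-12)
  # a stratum with too few subjects is skipped with a warning, not an error
  rec2 <- simulate_metric_records(rng_seed = 3)
  expect_warning(gt2 <- glm_group_test(rec2, "FA", age_split = 5),
                 "skipped")
  expect_false("<=5" %in% gt2$table$age_group)
})

test_that("partial correlations behave like residual correlations", {
  set.seed(5)
  n <- 30
  df <- tibble::tibble(age = runif(n, 3, 14), motion = runif(n, 0.5, 3))
  df$metric <- 0.3 + 0.01 * df$age - 0.02 * df$motion + rnorm(n, sd = 0.02)
  # behavior an exact affine function of the metric: r = 1
  df$behavior <- 5 - 40 * df$metric
  pc <- partial_correlation(df, "metric", "behavior")
  expect_equal(abs(pc$r), 1, tolerance = 1e-10)
  expect_equal(pc$df, n - 4)
  # r is invariant to covariate rescaling
  df2 <- df
  df2$age <- df2$age * 100
  df2$motion <- df2$motion - 50
  pc2 <- partial_correlation(df2, "metric", "behavior")
  expect_equal(pc2$r, pc$r, tolerance = 1e-10)
  # independent behavior: null-calibrated rejection rate
  seeds <- with(list(), {set.seed(77); sample.int(2^31 - 2, 500)})
  rej <- vapply(seeds, function(s) {
    set.seed(s)
    d <- tibble::tibble(age = runif(15, 3, 14), motion = runif(15, 0.5, 3),
                        x = rnorm(15), y = rnorm(15))
    partial_correlation(d, "x", "y")$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
  expect_error(partial_correlation(df[1:4, ], "metric", "behavior"), ">= 5")
})

test_that("empirical CDFs step correctly and shift under dominance", {
  cdf <- empirical_cdf(c(3, 1, 4, 2))
  expect_equal(cdf$cdf, c(0.25, 0.5, 0.75, 1))
  expect_equal(cdf$value, 1:4)
  expect_equal(max(cdf$cdf), 1)
  set.seed(1)
  a <- rnorm(50)
  b <- a + 1
  ca <- empirical_cdf(a); cb <- empirical_cdf(b)
  # shifted sample's CDF lies to the right
  grid <- seq(-2, 2, 0.25)
  Fa <- vapply(grid, function(x) mean(a <= x), 1)
  Fb <- vapply(grid, function(x) mean(b <= x), 1)
  expect_true(all(Fb <= Fa))
  expect_error(empirical_cdf(numeric()), "no finite")
})

test_that("flag tables report whole percentages with the expected calibration", {
  # B identical to A: the three-SE rule flags the reference-normal share
  # (mean - 3*SE at n = 14 is mean - 0.80 SD, ~21% of a normal reference)
  rec <- simulate_metric_records(n_per_group = c(14, 14), effect_sd = 0,
                                 rng_seed = 31)
  rec$FA[rec$group == "B"] <- rec$FA[rec$group == "A"]
  ft <- flag_table(rec, metrics = "FA")
  three <- ft[ft$criterion == "three_se", ]
  expect_true(all(three$percent >= 0 & three$percent <= 50))
  expect_true(all(ft$percent == round(ft$percent)))
  # a constructed cohort where exactly 11 of 15 B subjects lie below the
  # three-SE threshold reports 73%
  set.seed(41)
  ref <- as.numeric(scale(rnorm(14))) * 0.03 + 0.27
  thr <- mean(ref) - 3 * sd(ref) / sqrt(14)
  bvals <- c(rep(thr - 0.01, 11), rep(thr + 0.01, 4))
  rec2 <- tibble::tibble(
    subject = sprintf("S%02d", 1:29),
    group = rep(c("A", "B"), c(14, 15)),
    age = 6, motion = 1,
    pathway = "R_VDN",
    FA = c(ref, bvals))
  ft2 <- flag_table(rec2, metrics = "FA")
  expect_equal(ft2$percent[ft2$criterion == "three_se"], 73)
  expect_equal(ft2$n_flagged[ft2$criterion == "three_se"], 11)
  # leave-one-out lower-decile calibration on the reference group itself
  seeds <- with(list(), {set.seed(13); sample.int(2^31 - 2, 60)})
  loo <- vapply(seeds, function(s) {
    r <- simulate_metric_records(n_per_group = c(14, 2), effect_sd = 0,
                                 rng_seed = s)
    f <- flag_table(r, metrics = "FA", leave_one_out = TRUE)
    mean(f$n_flagged[f$criterion == "lower_decile"] /
           f$n_tested[f$criterion == "lower_decile"])
  }, 1)
  expect_gt(mean(loo), 0.03)
  expect_lt(mean(loo), 0.25)
})

test_that("age regressions return exact and null-calibrated R-squared", {
  df <- tibble::tibble(age = seq(3, 14, length.out = 14))
  df$density <- 0.3 - 0.01 * df$age
  ar <- suppressWarnings(age_regression(df, "density"))
  expect_equal(ar$r_squared, 1, tolerance = 1e-12)
  expect_equal(ar$slope, -0.01, tolerance = 1e-12)
  # negating the response flips the slope, not R^2
  df$neg <- -df$density
  ar2 <- suppressWarnings(age_regression(df, "neg"))
  expect_equal(ar2$r_squared, ar$r_squared)
  expect_equal(ar2$slope, 0.01, tolerance = 1e-12)
  # response independent of age: E[R^2] = 1/(n-1)
  set.seed(21)
  r2 <- replicate(1000, {
    d <- tibble::tibble(age = runif(14, 3, 14), y = rnorm(14))
    age_regression(d, "y")$r_squared
  })
  expect_equal(mean(r2), 1 / 13, tolerance = 0.15)
  dfc <- tibble::tibble(age = rep(5, 10), y = rnorm(10))
  expect_warning(arc <- age_regression(dfc, "y"), "constant")
  expect_true(is.na(arc$r_squared))
})
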