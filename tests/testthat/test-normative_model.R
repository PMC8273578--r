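test_that("the gamma age-conditional fit recovers the generating slope", {
  slopes <- vapply(1:5, function(s) {
    cohort <- normalize_cohort(generate_cohort(fs_config(seed = 400 + s)))
    m <- fit_normative(cohort, "gamma", volume_col = "left_hv_norm")
    m$beta_age
  }, numeric(1))
  # tolerance comparable to the half-width of the slope's reported CI
  expect_true(all(abs(slopes - (-0.008)) < 0.002))
})

test_that("the gamma fit agrees with the GLM mean-model oracle", {
  cohort <- normalize_cohort(generate_cohort(fs_config(seed = 21)))
  m <- fit_normative(cohort, "gamma", volume_col = "left_hv_norm")
  # in a gamma GLM with log link the mean coefficients are likelihood-optimal
  # for any fixed shape, so glm() is an independent oracle for (beta0, beta_age)
  glm_fit <- stats::glm(left_hv_norm ~ age, data = cohort,
                        family = stats::Gamma(link = "log"))
  expect_equal(m$beta0, unname(coef(glm_fit)[1]), tolerance = 1e-5)
  expect_equal(m$beta_age, unname(coef(glm_fit)[2]), tolerance = 1e-4)
})

test_that("the logistic age-conditional fit recovers its generating parameters", {
  cfg <- generator_config(seed = 31, n_cn = 532, family = "logistic",
                          location_link = "identity",
                          beta0 = 6500, beta_age = -20, dispersion = 300)
  cohort <- normalize_cohort(generate_cohort(cfg))
  m <- fit_normative(cohort, "logistic", volume_col = "left_hv_norm")
  expect_lt(abs(m$beta_age - (-20)), 3 * sqrt(m$vcov[2, 2]))
  expect_lt(abs(m$dispersion - 300) / 300, 0.1)
})

test_that("a zero-slope cohort is recovered without a monotonicity warning", {
  hits <- vapply(1:10, function(s) {
    cfg <- generator_config(seed = 100 + s, n_cn = 300, beta_age = 0,
                            beta0 = log(3600))
    cohort <- normalize_cohort(generate_cohort(cfg))
    m <- suppressWarnings(fit_normative(cohort, "gamma",
                                        volume_col = "left_hv_norm"))
    abs(m$beta_age) < 2 * sqrt(m$vcov[2, 2])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("degenerate designs are refused", {
  cohort <- normalize_cohort(generate_cohort(fs_config(seed = 8, n = 100)))
  cohort$age <- 70
  expect_error(fit_normative(cohort, "gamma", volume_col = "left_hv_norm"),
               "ages span")
  small <- normalize_cohort(generate_cohort(fs_config(seed = 8, n = 30)))
  expect_error(fit_normative(small, "gamma", volume_col = "left_hv_norm"),
               "at least 50")
})

test_that("predict_quantile matches brute-force CDF inversion", {
  m <- fitted_fs_model(seed = 7)
  levels <- c(5, 10, 25, 50, 75, 90, 95)
  for (a in c(57, 65, 75, 89)) {
    for (lv in levels) {
      q <- predict_quantile(m, a, lv / 100)
      oracle <- uniroot(function(v) subject_percentile(m, a, v) / 100 - lv / 100,
                        interval = c(100, 30000), tol = 1e-9)$root
      expect_equal(q, oracle, tolerance = 1e-6)
    }
  }
  expect_error(predict_quantile(m, 70, 1.5), "inside")
})

test_that("with zero slope the conditional quantile collapses to the marginal family", {
  m <- fitted_fs_model(seed = 7)
  m0 <- m
  m0$beta_age <- 0
  fam <- hn_family("gamma", exp(m0$beta0), m0$dispersion)
  for (p in c(0.05, 0.5, 0.95)) {
    q <- predict_quantile(m0, c(60, 75, 89), p)
    expect_lt(max(abs(q - hn_quantile(fam, p))), 1e-9)
    expect_equal(q[1], q[3])
  }
})

test_that("threshold tables are element-wise consistent with predict_quantile", {
  m <- fitted_fs_model(seed = 7)
  tab <- make_threshold_table(m, digits = NULL)
  expect_equal(nrow(tab), 35 * 7)
  direct <- suppressWarnings(
    predict_quantile(m, tab$age, tab$level / 100, extrapolate = TRUE))
  expect_equal(tab$threshold, direct)
  # declining model: every level non-increasing over age
  by_level <- split(tab$threshold[order(tab$level, tab$age)],
                    sort(tab$level))
  for (th in by_level) expect_true(all(diff(th) < 0))
  single <- make_threshold_table(m, levels = 50)
  expect_equal(unique(single$level), 50)
})

test_that("tabulated thresholds default to integer mm3", {
  m <- fitted_fs_model(seed = 7)
  tab <- make_threshold_table(m)
  expect_equal(tab$threshold, round(tab$threshold))
})

test_that("expected volume is the model median and matches simulation", {
  cfg <- generator_config(seed = 32, n_cn = 532, family = "logistic",
                          location_link = "identity",
                          beta0 = 6500, beta_age = -20, dispersion = 300)
  cohort <- normalize_cohort(generate_cohort(cfg))
  ml <- fit_normative(cohort, "logistic", volume_col = "left_hv_norm")
  expect_equal(expected_volume(ml, 73), ml$beta0 + ml$beta_age * 73)
  m <- fitted_fs_model(seed = 7)
  ev <- expected_volume(m, 73)
  expect_equal(subject_percentile(m, 73, ev), 50, tolerance = 1e-9)
  set.seed(9)
  shape <- 1 / m$dispersion^2
  draws <- rgamma(1e5, shape = shape,
                  rate = shape / exp(m$beta0 + m$beta_age * 73))
  expect_lt(abs(median(draws) - ev), 6)   # ~3 x SE of the sample median
  # mean option returns the distribution mean instead
  expect_equal(expected_volume(m, 73, type = "mean"),
               exp(m$beta0 + m$beta_age * 73))
})

test_that("real-vs-computed comparison is calibrated and detects shifts", {
  m <- fitted_fs_model(seed = 7)
  covered <- vapply(1:100, function(s) {
    cohort <- normalize_cohort(generate_cohort(fs_config(seed = 2000 + s,
                                                         n = 64)))
    cmp <- compare_real_vs_computed(cohort, m, volume_col = "left_hv_norm")
    cmp$similar
  }, logical(1))
  expect_gte(mean(covered), 0.9)
  shifted <- normalize_cohort(generate_cohort(fs_config(seed = 33, n = 64)))
  shifted$left_hv_norm <- shifted$left_hv_norm + 500
  cmp <- compare_real_vs_computed(shifted, m, volume_col = "left_hv_norm")
  expect_false(cmp$similar)
  expect_lt(abs(cmp$mean_diff - 500), 150)
  one <- shifted[1, ]
  expect_error(compare_real_vs_computed(one, m, volume_col = "left_hv_norm"),
               "at least 2")
})

test_that("in-sample coverage is calibrated to within a few percentage points", {
  # the failure rate of the 3-pp bound is itself ~5%; guard it with a
  # one-sided binomial criterion rather than a point threshold
  reps <- 40
  fails <- sum(vapply(seq_len(reps), function(s) {
    cohort <- normalize_cohort(generate_cohort(fs_config(seed = 3000 + s)))
    m <- fit_normative(cohort, "gamma", volume_col = "left_hv_norm")
    cv <- coverage_check(m, cohort, volume_col = "left_hv_norm")
    attr(cv, "max_discrepancy_pp") >= 3
  }, logical(1)))
  expect_lte(fails, qbinom(0.995, reps, 0.05))
})

test_that("a cohort far above the curves has zero coverage and tiny p-values", {
  m <- fitted_fs_model(seed = 7)
  cohort <- normalize_cohort(generate_cohort(fs_config(seed = 12, n = 500)))
  cohort$left_hv_norm <- cohort$left_hv_norm + 5000
  cv <- coverage_check(m, cohort, volume_col = "left_hv_norm")
  expect_true(all(cv$observed_below == 0))
  expect_lt(max(cv$p_value), 1e-4)
})

test_that("the log-linear age regression reports the generating slope", {
  cohort <- normalize_cohort(generate_cohort(fs_config(seed = 44)))
  reg <- age_slope_regression(cohort, volume_col = "left_hv_norm")
  expect_lt(abs(reg$slope - (-0.008)), 0.003)
  expect_lt(reg$p_value, 0.001)
})

test_that("tidy and glance expose the fitted parameters", {
  m <- fitted_fs_model(seed = 7, n = 200)
  td <- tidy(m)
  expect_equal(td$term, c("beta0", "beta_age", "dispersion"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(m)
  expect_equal(gl$nobs, 200)
  expect_equal(gl$AIC, 6 - 2 * m$loglik)
})
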