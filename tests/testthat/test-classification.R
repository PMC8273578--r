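test_that("percentile lookup is exact at the median and at the cut-off boundary", {
  m <- fitted_fs_model(seed = 7)
  med <- predict_quantile(m, 70, 0.5)
  expect_equal(subject_percentile(m, 70, med), 50, tolerance = 1e-9)
  q5 <- predict_quantile(m, 70, 0.05)
  expect_lt(subject_percentile(m, 70, q5 - 1e-6), 5)
  expect_gte(subject_percentile(m, 70, q5 + 1e-6), 5)
})

test_that("percentile lookup matches direct CDF evaluation and is monotone in volume", {
  m <- fitted_fs_model(seed = 7)
  set.seed(55)
  for (i in 1:20) {
    a <- runif(1, 57, 89)
    v <- runif(1, 2000, 5500)
    fam <- hn_family("gamma", exp(m$beta0 + m$beta_age * a), m$dispersion)
    expect_equal(subject_percentile(m, a, v), 100 * hn_cdf(fam, v),
                 tolerance = 1e-9)
  }
  vols <- seq(2000, 5500, by = 250)
  expect_true(all(diff(subject_percentile(m, 70, vols)) > 0))
})

test_that("ages far outside the fitted range need the extrapolation flag", {
  m <- fitted_fs_model(seed = 7)
  expect_error(subject_percentile(m, 110, 3000), "extrapolate")
  expect_warning(subject_percentile(m, 92, 3000), "outside the fitted range")
  expect_silent(subject_percentile(m, 110, 3000, extrapolate = TRUE))
})

test_that("abnormality flags against published anchors use the printed cut-offs", {
  norms <- load_published_norms()
  res <- flag_abnormal(norms$FS_left, age = 56, volume = 3200)
  expect_true(res$abnormal)
  expect_equal(res$cutoff_applied, 3223)
  expect_identical(res$norms_provenance, "published_anchor")
  # a volume exactly at the threshold is NOT below it
  tie <- flag_abnormal(norms$AA_right, age = 90, volume = 3870)
  expect_false(tie$abnormal)
  expect_error(flag_abnormal(norms$FS_left, age = 70, volume = 3200),
               "No published anchor")
})

test_that("flags against a fitted model respect the strict-inequality boundary", {
  m <- fitted_fs_model(seed = 7)
  cutoff <- predict_quantile(m, 70, 0.05)
  below <- flag_abnormal(m, 70, cutoff - 1)
  above <- flag_abnormal(m, 70, cutoff + 1)
  expect_true(below$abnormal)
  expect_false(above$abnormal)
  expect_equal(below$cutoff_applied, cutoff)
})

test_that("flagging agrees with the percentile comparison wherever both are defined", {
  m <- fitted_fs_model(seed = 7)
  set.seed(66)
  age <- runif(200, 57, 89)
  vol <- runif(200, 2200, 5200)
  res <- flag_abnormal(m, age, vol)
  expect_equal(res$abnormal, res$percentile < res$level)
})

test_that("model-drawn percentiles are uniform (probability integral transform)", {
  m <- fitted_fs_model(seed = 7)
  set.seed(77)
  n <- 10000
  age <- runif(n, m$age_range[1], m$age_range[2])
  shape <- 1 / m$dispersion^2
  vol <- rgamma(n, shape = shape,
                rate = shape / exp(m$beta0 + m$beta_age * age))
  pct <- subject_percentile(m, age, vol)
  ks <- suppressWarnings(stats::ks.test(pct / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("group summaries centre the reference group at the 50th percentile", {
  m <- fitted_fs_model(seed = 7)
  set.seed(88)
  n <- 2000
  age <- runif(n, m$age_range[1], m$age_range[2])
  shape <- 1 / m$dispersion^2
  vol <- rgamma(n, shape = shape,
                rate = shape / exp(m$beta0 + m$beta_age * age))
  data <- tibble::tibble(age = age, volume = vol, diagnosis = "CN")
  out <- group_percentile_summary(data, m)
  expect_equal(nrow(out), 1)
  expect_lt(abs(out$mean_percentile - 50), 2)
  # a downward shift of 1.5 dispersion units drags the mean percentile down
  shifted <- dplyr::mutate(data,
                           volume = .data$volume - 1.5 * m$dispersion *
                             exp(m$beta0 + m$beta_age * .data$age),
                           diagnosis = "AD")
  both <- dplyr::bind_rows(data, shifted)
  out2 <- group_percentile_summary(both, m)
  expect_lt(out2$mean_percentile[out2$diagnosis == "AD"], 25)
})

test_that("Cohen's kappa reproduces hand-computed agreement", {
  # identical flags, both classes present
  a <- c(rep(TRUE, 10), rep(FALSE, 90))
  expect_equal(cohens_kappa(a, a), 1)
  # TP=10 FP=5 FN=5 TN=80: po = 0.90, pe = 0.745, kappa = 0.155/0.255
  x <- c(rep(TRUE, 10), rep(TRUE, 5), rep(FALSE, 5), rep(FALSE, 80))
  y <- c(rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 80))
  expect_equal(cohens_kappa(x, y), (0.90 - 0.745) / (1 - 0.745),
               tolerance = 1e-12)
  expect_equal(round(cohens_kappa(x, y), 4), 0.6078)
})

test_that("kappa is symmetric and near zero for independent raters", {
  set.seed(99)
  a <- runif(10000) < 0.3
  b <- runif(10000) < 0.3
  k <- cohens_kappa(a, b)
  expect_lt(abs(k), 0.03)
  expect_equal(k, cohens_kappa(b, a))
})

test_that("degenerate kappa marginals are handled explicitly", {
  expect_equal(cohens_kappa(rep(TRUE, 5), rep(TRUE, 5)), 1)
  expect_error(cohens_kappa(rep(TRUE, 5), c(TRUE, TRUE, TRUE, TRUE, FALSE)),
               NA)   # non-degenerate: second rater has two classes
  expect_error(cohens_kappa(c(TRUE, FALSE), c(FALSE, TRUE)), NA)
})

test_that("diagnostic metrics reproduce the confusion-table identities", {
  truth <- c(rep(TRUE, 3), rep(FALSE, 97))
  flags <- c(rep(TRUE, 5), rep(FALSE, 95))   # TP=3 FP=2 FN=0 TN=95
  dm <- diagnostic_metrics(flags, truth)
  got <- setNames(dm$metrics$value, dm$metrics$metric)
  expect_equal(unname(got["Se"]), 1)
  expect_equal(unname(got["Sp"]), 95 / 97)
  expect_equal(unname(got["PPV"]), 0.6)
  expect_equal(unname(got["NPV"]), 1)
  expect_equal(dm$counts$n, 100)
  # perfect agreement
  dm2 <- diagnostic_metrics(truth, truth)
  expect_true(all(dm2$metrics$value == 1))
  # all-negative flags: Se = 0, PPV undefined (NA, not 0)
  dm3 <- diagnostic_metrics(rep(FALSE, 100), truth)
  got3 <- setNames(dm3$metrics$value, dm3$metrics$metric)
  expect_equal(unname(got3["Se"]), 0)
  expect_true(is.na(got3["PPV"]))
})

test_that("metric identities hold on random confusion tables", {
  set.seed(111)
  for (i in 1:20) {
    flags <- runif(60) < runif(1, 0.2, 0.8)
    truth <- runif(60) < runif(1, 0.2, 0.8)
    dm <- diagnostic_metrics(flags, truth)
    with(dm$counts, {
      expect_equal(TP + FP + TN + FN, 60)
      got <- setNames(dm$metrics$value, dm$metrics$metric)
      if (TP + FN > 0) expect_equal(unname(got["Se"]), TP / (TP + FN))
      if (TN + FP > 0) expect_equal(unname(got["Sp"]), TN / (TN + FP))
    })
  }
})

test_that("outer-percentile discrepancy tests match stats::chisq.test", {
  pct <- c(rep(2, 3), rep(50, 94), rep(97, 3))   # 3% below 5th, 3% above 95th
  dm <- diagnostic_metrics(rep(FALSE, 100), rep(FALSE, 100),
                           percentiles = pct)
  ref <- suppressWarnings(stats::chisq.test(c(3, 97), p = c(0.05, 0.95)))
  expect_equal(dm$tail_tests$statistic[1], unname(ref$statistic))
  expect_equal(dm$tail_tests$p_value[1], ref$p.value)
  expect_equal(round(dm$tail_tests$p_value[1], 3), 0.359)
})

test_that("the single-case report carries the classification verdict", {
  m <- fitted_fs_model(seed = 7)
  res <- flag_abnormal(m, 70, 2500, subject_id = "P001")
  rep <- single_case_report(res)
  expect_match(rep$text, "ABNORMAL")
  expect_match(rep$text, "P001")
  expect_equal(rep$report$subject_id, "P001")
})
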