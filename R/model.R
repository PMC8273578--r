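#' Fit an age-conditional normative percentile model
#'
#' Fits, by direct maximum likelihood, a distributional regression of
#' (normalized) hippocampal volume on age with a linear location predictor
#' and constant dispersion — the minimal location/scale model behind
#' age-indexed percentile growth charts. For the Gamma family the mean is
#' modelled on the log scale, `log mu(age) = beta0 + beta_age * age`, with
#' constant coefficient of variation; for the Logistic family the location is
#' linear in age on the identity scale with constant scale. Hippocampal
#' volumes decline with age in adults, so a fitted positive age slope raises
#' a warning.
#'
#' @param data A tibble with an age column and a volume column (normalized
#'   volumes are the intended input; see [normalize_cohort()]).
#' @param family `"gamma"` or `"logistic"`.
#' @param volume_col,age_col Column names (strings). Defaults `"volume"`,
#'   `"age"`.
#' @param tool,hemisphere Optional labels stored in the model and propagated
#'   to threshold tables.
#' @return An object of class `hn_model`: a list with `family`,
#'   `location_link`, `beta0`, `beta_age`, `dispersion`, `fit_n`, `loglik`,
#'   `age_range`, `convergence`, `vcov` (observed-information covariance of
#'   `(beta0, beta_age, log dispersion)`).
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 1, n_cn = 200))
#' fit_normative(cohort, "gamma", volume_col = "left_hv")
#' @export
fit_normative <- function(data, family = c("gamma", "logistic"),
                          volume_col = "volume", age_col = "age",
                          tool = NA_character_, hemisphere = NA_character_) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data))
  for (cl in c(volume_col, age_col)) {
    if (!cl %in% names(data)) abort(sprintf("Column '%s' not found.", cl))
  }
  v <- as.numeric(data[[volume_col]])
  age <- as.numeric(data[[age_col]])
  keep <- is.finite(v) & is.finite(age)
  v <- v[keep]; age <- age[keep]
  n <- length(v)
  if (n < 50L) abort(sprintf("Need at least 50 complete records to fit a normative model (got %d).", n))
  if (diff(range(age)) < 10) abort("ages span < 10 years; an age-conditional model cannot be identified.")
  if (family == "gamma" && any(v <= 0)) {
    abort("Gamma family requires strictly positive volumes.")
  }

  # the age covariate is centred internally: the raw intercept (volume at
  # age 0) is nearly collinear with the slope over an adult age range and
  # stalls gradient methods
  ctr <- mean(age)
  age_c <- age - ctr
  # deterministic moment/least-squares initialization
  if (family == "gamma") {
    init_fit <- lm(log(v) ~ age_c)
    init <- c(coef(init_fit), log(max(sd(init_fit$residuals), 1e-6)))
    negll <- function(par) {
      mu <- exp(par[1] + par[2] * age_c)
      shape <- exp(-2 * par[3])            # sigma = CV, shape = 1/sigma^2
      ll <- suppressWarnings(
        sum(dgamma(v, shape = shape, rate = shape / mu, log = TRUE)))
      if (!is.finite(ll)) return(.Machine$double.xmax / 1e10)
      -ll
    }
  } else {
    init_fit <- lm(v ~ age_c)
    s0 <- max(sd(init_fit$residuals) * sqrt(3) / pi, 1e-6)
    init <- c(coef(init_fit), log(s0))
    negll <- function(par) {
      ll <- suppressWarnings(
        sum(dlogis(v, location = par[1] + par[2] * age_c,
                   scale = exp(par[3]), log = TRUE)))
      if (!is.finite(ll)) return(.Machine$double.xmax / 1e10)
      -ll
    }
  }
  names(init) <- c("beta0", "beta_age", "log_dispersion")
  opt <- optim(init, negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-14))
  grad_norm <- max(abs(numeric_grad(negll, opt$par)))
  if (opt$convergence != 0 || !is.finite(opt$value)) {
    abort(sprintf(
      "Normative fit did not converge (optim code %d, %d evaluations, gradient norm %.3g).",
      opt$convergence, opt$counts[1], grad_norm))
  }
  vcov_c <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, 3, 3)
  })
  # back-transform intercept and covariance to the uncentred scale
  J <- diag(3); J[1, 2] <- -ctr
  vcov <- J %*% vcov_c %*% t(J)
  opt$par["beta0"] <- opt$par["beta0"] - ctr * opt$par["beta_age"]
  beta_age <- unname(opt$par["beta_age"])
  if (beta_age > 0) {
    warn("Fitted age slope is positive: the expected monotone decline of hippocampal volume with age is violated.")
  }
  model <- structure(list(
    family = family,
    location_link = if (family == "gamma") "log" else "identity",
    beta0 = unname(opt$par["beta0"]),
    beta_age = beta_age,
    dispersion = exp(unname(opt$par["log_dispersion"])),
    fit_n = n,
    loglik = -opt$value,
    age_range = range(age),
    convergence = list(code = opt$convergence, evaluations = opt$counts,
                       gradient_norm = grad_norm),
    vcov = vcov,
    tool = tool, hemisphere = hemisphere
  ), class = "hn_model")
  # a fitted model must never produce crossing percentile curves
  check_level_monotone(make_threshold_table(
    model, ages = seq(model$age_range[1], model$age_range[2], length.out = 8),
    digits = NULL))
  model
}

numeric_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' @export
print.hn_model <- function(x, ...) {
  cat(sprintf("<hn_model> %s family, %s-link location\n", x$family,
              x$location_link))
  cat(sprintf("  location(age) = %s(%.5f %+.5f * age), dispersion = %.5f\n",
              if (x$location_link == "log") "exp" else "", x$beta0,
              x$beta_age, x$dispersion))
  cat(sprintf("  n = %d, logLik = %.2f, age range %g-%g\n", x$fit_n,
              x$loglik, x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' @export
tidy.hn_model <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  est <- c(x$beta0, x$beta_age, x$dispersion)
  # dispersion was optimized on the log scale; delta-method SE
  se[3] <- se[3] * x$dispersion
  tibble::tibble(
    term = c("beta0", "beta_age", "dispersion"),
    estimate = est,
    std.error = se,
    conf.low = est - qnorm(0.975) * se,
    conf.high = est + qnorm(0.975) * se
  )
}

#' @export
glance.hn_model <- function(x, ...) {
  tibble::tibble(
    family = x$family, location_link = x$location_link,
    nobs = x$fit_n, logLik = x$loglik,
    AIC = 2 * 3 - 2 * x$loglik,
    age_min = x$age_range[1], age_max = x$age_range[2]
  )
}

# family object at one age under an hn_model
family_at_age <- function(model, age) {
  loc <- if (model$location_link == "log") {
    exp(model$beta0 + model$beta_age * age)
  } else {
    model$beta0 + model$beta_age * age
  }
  loc
}

check_age <- function(model, age, extrapolate, slack = 0) {
  lo <- model$age_range[1] - slack
  hi <- model$age_range[2] + slack
  outside <- age < lo | age > hi
  if (any(outside)) {
    if (extrapolate) {
      warn(sprintf("Age(s) outside the fitted range %g-%g; extrapolating the percentile curves.",
                   model$age_range[1], model$age_range[2]))
    } else {
      abort(sprintf("Age(s) outside the supported range %g-%g; set `extrapolate = TRUE` to override.",
                    lo, hi))
    }
  }
  invisible(TRUE)
}

#' Age-specific percentile threshold of a fitted model
#'
#' Evaluates the family quantile at the age-specific location with the
#' model's constant dispersion. Strictly increasing in `p`; decreasing in
#' age whenever the fitted slope is negative.
#'
#' @param model An [fit_normative()] result.
#' @param age Age(s) in years.
#' @param p Probability(ies) in (0, 1). `age` and `p` are recycled to a
#'   common length.
#' @param extrapolate Allow ages outside the fitted range (with a warning).
#' @return Volume threshold(s) in mm3.
#' @export
predict_quantile <- function(model, age, p, extrapolate = FALSE) {
  stopifnot(inherits(model, "hn_model"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1).")
  }
  check_age(model, age, extrapolate)
  quantile_core(model, age, p)
}

quantile_core <- function(model, age, p) {
  k <- max(length(age), length(p))
  age <- rep_len(age, k); p <- rep_len(p, k)
  loc <- family_at_age(model, age)
  if (model$family == "gamma") {
    shape <- 1 / model$dispersion^2
    qgamma(p, shape = shape, rate = shape / loc)
  } else {
    qlogis(p, location = loc, scale = model$dispersion)
  }
}

#' Expected (typical) volume at a given age
#'
#' The model's central prediction for a subject of the given age: the median
#' by default (link-free and consistent with the percentile curves), or the
#' distribution mean.
#'
#' @inheritParams predict_quantile
#' @param type `"median"` (default) or `"mean"`.
#' @return Volume(s) in mm3.
#' @export
expected_volume <- function(model, age, type = c("median", "mean"),
                            extrapolate = FALSE) {
  type <- match.arg(type)
  if (type == "median") {
    return(predict_quantile(model, age, 0.5, extrapolate = extrapolate))
  }
  check_age(model, age, extrapolate)
  family_at_age(model, age)   # mean for gamma; mean = location for logistic
}

#' Tabulate percentile thresholds over an age grid
#'
#' Evaluates [predict_quantile()] on an age-by-level grid and packages the
#' result as a [percentile_table()] (provenance `"fitted"`). By default the
#' tabulated thresholds are rounded to the nearest integer mm3, the
#' resolution at which such norms are conventionally reported; pass
#' `digits = NULL` to keep full precision.
#'
#' @param model An [fit_normative()] result.
#' @param ages Integer age grid; default 56:90.
#' @param levels Percentile levels in percent; default
#'   `c(5, 10, 25, 50, 75, 90, 95)`.
#' @param digits Rounding of tabulated thresholds (default 0 = integer mm3);
#'   `NULL` for no rounding.
#' @param extrapolate Allow grid ages outside the fitted range.
#' @return An `hn_percentile_table`.
#' @export
make_threshold_table <- function(model, ages = 56:90,
                                 levels = c(5, 10, 25, 50, 75, 90, 95),
                                 digits = 0L, extrapolate = FALSE) {
  stopifnot(inherits(model, "hn_model"))
  grid <- tidyr::expand_grid(age = as.numeric(ages),
                             level = as.numeric(levels))
  # a tabulation grid may poke one year past the observed age range (a
  # cohort rarely samples the exact integer endpoints) without counting as
  # extrapolation
  check_age(model, grid$age, extrapolate, slack = 1)
  grid$threshold <- quantile_core(model, grid$age, grid$level / 100)
  if (!is.null(digits)) grid$threshold <- round(grid$threshold, digits)
  percentile_table(grid,
                   tool = if (is.na(model$tool)) "FS" else model$tool,
                   hemisphere = if (is.na(model$hemisphere)) "left" else model$hemisphere,
                   provenance = "fitted")
}

#' Compare observed volumes with model-expected volumes
#'
#' For every subject the difference `observed - expected` is formed, where
#' the expected volume comes from [expected_volume()] at the subject's age;
#' the mean difference, its t-based 95 percent confidence interval and the
#' two-sided paired test p-value are returned. A confidence interval
#' containing zero is the operational meaning of "the cohort matches the
#' norms".
#'
#' @param data Tibble with age and volume columns.
#' @param model An [fit_normative()] result.
#' @inheritParams fit_normative
#' @param conf_level Confidence level (default 0.95).
#' @param extrapolate Allow ages outside the fitted range.
#' @return A one-row tibble: `n`, `mean_diff`, `conf.low`, `conf.high`,
#'   `p_value`, `similar` (logical: CI contains 0).
#' @export
compare_real_vs_computed <- function(data, model, volume_col = "volume",
                                     age_col = "age", conf_level = 0.95,
                                     extrapolate = FALSE) {
  stopifnot(is.data.frame(data), inherits(model, "hn_model"))
  v <- as.numeric(data[[volume_col]])
  age <- as.numeric(data[[age_col]])
  keep <- is.finite(v) & is.finite(age)
  v <- v[keep]; age <- age[keep]
  if (length(v) < 2L) {
    abort("Need at least 2 subjects: the CI of the mean difference is undefined otherwise.")
  }
  check_age(model, age, extrapolate, slack = 1)
  expected <- quantile_core(model, age, 0.5)
  tt <- t.test(v - expected, conf.level = conf_level)
  tibble::tibble(
    n = length(v),
    mean_diff = unname(tt$estimate),
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2],
    p_value = tt$p.value,
    similar = tt$conf.int[1] <= 0 && tt$conf.int[2] >= 0
  )
}

#' Percentile-coverage calibration of a fitted model
#'
#' For each percentile level, counts the fraction of a cohort falling
#' strictly below its age-specific threshold curve and compares it with the
#' nominal level by a one-degree-of-freedom chi-square test on the
#' below/above counts. A well-calibrated model has observed coverage close
#' to nominal at every level; the maximum discrepancy is reported in
#' percentage points.
#'
#' @param model An [fit_normative()] result.
#' @param data Tibble with age and volume columns (`n >= 100`).
#' @inheritParams fit_normative
#' @param levels Percentile levels in percent.
#' @param extrapolate Allow ages outside the fitted range.
#' @return A tibble of class `hn_coverage`, one row per level: `level`,
#'   `n`, `observed_below`, `observed_pct`, `expected_pct`,
#'   `discrepancy_pp`, `statistic`, `dof`, `p_value`; the maximum
#'   discrepancy is the `max_discrepancy_pp` attribute.
#' @export
coverage_check <- function(model, data, volume_col = "volume",
                           age_col = "age",
                           levels = c(5, 10, 25, 50, 75, 90, 95),
                           extrapolate = FALSE) {
  stopifnot(is.data.frame(data), inherits(model, "hn_model"))
  v <- as.numeric(data[[volume_col]])
  age <- as.numeric(data[[age_col]])
  keep <- is.finite(v) & is.finite(age)
  v <- v[keep]; age <- age[keep]
  n <- length(v)
  if (n < 100L) abort("Coverage checks need at least 100 subjects.")
  check_age(model, age, extrapolate, slack = 1)
  rows <- purrr::map(levels, function(lv) {
    thr <- quantile_core(model, age, lv / 100)
    below <- sum(v < thr)
    expected <- n * lv / 100
    statistic <- (below - expected)^2 / expected +
      ((n - below) - (n - expected))^2 / (n - expected)
    tibble::tibble(
      level = lv, n = n, observed_below = below,
      observed_pct = 100 * below / n, expected_pct = lv,
      discrepancy_pp = abs(100 * below / n - lv),
      statistic = statistic, dof = 1L,
      p_value = pchisq(statistic, df = 1, lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "max_discrepancy_pp") <- max(out$discrepancy_pp)
  class(out) <- c("hn_coverage", class(out))
  out
}

#' Log-linear regression of volume on age
#'
#' The descriptive association check that accompanies the normative model:
#' volumes are log-transformed (their distribution is right-skewed) and
#' regressed on age by least squares. The age coefficient is the per-year
#' relative decline.
#'
#' @param data Tibble with age and volume columns.
#' @inheritParams fit_normative
#' @param conf_level Confidence level for the slope interval.
#' @return A one-row tibble: `slope`, `conf.low`, `conf.high`, `p_value`,
#'   `n`.
#' @export
age_slope_regression <- function(data, volume_col = "volume",
                                 age_col = "age", conf_level = 0.95) {
  v <- as.numeric(data[[volume_col]])
  age <- as.numeric(data[[age_col]])
  keep <- is.finite(v) & is.finite(age) & v > 0
  fit <- lm(log(v[keep]) ~ age[keep])
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  tibble::tibble(
    slope = sm[2, 1], conf.low = ci[2, 1], conf.high = ci[2, 2],
    p_value = sm[2, 4], n = sum(keep)
  )
}
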