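#' Distribution family parameters for normative volumetry
#'
#' Constructs the parameter object used throughout the package to describe the
#' residual distribution of (normalized) hippocampal volumes. Two families are
#' first-class citizens — Gamma for FreeSurfer-like volumes and Logistic for
#' ACM-Adaboost-like volumes — plus the log-normal as a sanity alternative in
#' family ranking.
#'
#' The Gamma family is parameterized by its mean and a dispersion equal to the
#' coefficient of variation, i.e. `shape = 1 / dispersion^2` and
#' `rate = shape / mean`. This mean parameterization is what makes a log link
#' on the location natural in the age-conditional model. The Logistic family
#' uses the usual (location, scale) and the log-normal (meanlog, sdlog).
#'
#' @param family One of `"gamma"`, `"logistic"`, `"lognormal"`.
#' @param location Family location: the mean for Gamma (must be > 0), the
#'   location for Logistic, the meanlog for log-normal.
#' @param dispersion Family dispersion: coefficient of variation for Gamma,
#'   scale for Logistic, sdlog for log-normal. Must be > 0.
#' @param n_fitted Number of parameters estimated from data (0 for parameters
#'   fixed a priori, 2 for a maximum-likelihood fit). Used by [chi2_gof()] to
#'   set the degrees of freedom.
#'
#' @return An object of class `hn_family`.
#' @examples
#' fam <- hn_family("logistic", location = 5000, dispersion = 300)
#' hn_quantile(fam, 0.5)
#' @export
hn_family <- function(family = c("gamma", "logistic", "lognormal"),
                      location, dispersion, n_fitted = 0L) {
  family <- match.arg(family)
  if (!is.numeric(location) || length(location) != 1L || !is.finite(location)) {
    abort("`location` must be a single finite number.")
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1L ||
      !is.finite(dispersion) || dispersion <= 0) {
    abort("`dispersion` must be a single positive number.")
  }
  if (family == "gamma" && location <= 0) {
    abort("Gamma family requires a positive mean (`location` > 0).")
  }
  structure(
    list(family = family, location = location, dispersion = dispersion,
         n_fitted = as.integer(n_fitted)),
    class = "hn_family"
  )
}

#' @export
print.hn_family <- function(x, ...) {
  cat(sprintf("<hn_family> %s(location = %g, dispersion = %g)\n",
              x$family, x$location, x$dispersion))
  invisible(x)
}

# shape/rate view of the mean-CV gamma parameterization
gamma_shape_rate <- function(fam) {
  shape <- 1 / fam$dispersion^2
  list(shape = shape, rate = shape / fam$location)
}

#' Density, CDF, quantile and sampling for a family object
#'
#' Thin vectorized wrappers dispatching on the `hn_family` parameterization.
#' `hn_quantile()` is strictly increasing in `p` and inverse-consistent with
#' `hn_cdf()` to high accuracy for both families.
#'
#' @param fam An [hn_family()] object.
#' @param x,q,p,n Evaluation points, probabilities in (0, 1), or sample size.
#' @return Numeric vector (`hn_sample()` draws using the current RNG stream).
#' @name family-functions
NULL

#' @rdname family-functions
#' @export
hn_density <- function(fam, x) {
  stopifnot(inherits(fam, "hn_family"))
  switch(fam$family,
    gamma = {
      sr <- gamma_shape_rate(fam)
      dgamma(x, shape = sr$shape, rate = sr$rate)
    },
    logistic = dlogis(x, fam$location, fam$dispersion),
    lognormal = dlnorm(x, fam$location, fam$dispersion)
  )
}

#' @rdname family-functions
#' @export
hn_cdf <- function(fam, q) {
  stopifnot(inherits(fam, "hn_family"))
  switch(fam$family,
    gamma = {
      sr <- gamma_shape_rate(fam)
      pgamma(q, shape = sr$shape, rate = sr$rate)
    },
    logistic = plogis(q, fam$location, fam$dispersion),
    lognormal = plnorm(q, fam$location, fam$dispersion)
  )
}

#' @rdname family-functions
#' @export
hn_quantile <- function(fam, p) {
  stopifnot(inherits(fam, "hn_family"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1).")
  }
  switch(fam$family,
    gamma = {
      sr <- gamma_shape_rate(fam)
      qgamma(p, shape = sr$shape, rate = sr$rate)
    },
    logistic = qlogis(p, fam$location, fam$dispersion),
    lognormal = qlnorm(p, fam$location, fam$dispersion)
  )
}

#' @rdname family-functions
#' @export
hn_sample <- function(fam, n) {
  stopifnot(inherits(fam, "hn_family"))
  switch(fam$family,
    gamma = {
      sr <- gamma_shape_rate(fam)
      rgamma(n, shape = sr$shape, rate = sr$rate)
    },
    logistic = rlogis(n, fam$location, fam$dispersion),
    lognormal = rlnorm(n, fam$location, fam$dispersion)
  )
}

#' Maximum-likelihood fit of a single family to a volume sample
#'
#' Fits one marginal distribution family to a sample of volumes by maximum
#' likelihood (via \pkg{fitdistrplus}) and returns the result in the package's
#' mean/dispersion parameterization together with the attained log-likelihood.
#'
#' @param samples Numeric sample, `n >= 10`; strictly positive for the Gamma
#'   and log-normal families.
#' @param family Family name as in [hn_family()].
#' @return An [hn_family()] object with `n_fitted = 2` and attributes
#'   `loglik` (maximized log-likelihood) and `n` (sample size).
#' @examples
#' set.seed(1)
#' mle_fit(rlogis(500, 5000, 300), "logistic")
#' @export
mle_fit <- function(samples, family = c("gamma", "logistic", "lognormal")) {
  family <- match.arg(family)
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("`samples` must be finite and non-missing.")
  }
  if (length(samples) < 10L) abort("Need at least 10 observations to fit.")
  if (family %in% c("gamma", "lognormal") && any(samples <= 0)) {
    abort(sprintf("The %s family requires strictly positive samples.", family))
  }
  if (sd(samples) == 0) {
    abort("Degenerate sample (zero variance); no dispersion can be estimated.")
  }
  distr <- switch(family, gamma = "gamma", logistic = "logis",
                  lognormal = "lnorm")
  fit <- tryCatch(
    suppressWarnings(fitdistrplus::fitdist(samples, distr)),
    error = function(e) {
      abort(sprintf("Maximum-likelihood fit of the %s family failed: %s",
                    family, conditionMessage(e)))
    }
  )
  if (!is.finite(fit$loglik)) {
    abort(sprintf("Maximum-likelihood fit of the %s family did not converge.",
                  family))
  }
  est <- coef(fit)
  fam <- switch(family,
    gamma = hn_family("gamma",
                      location = unname(est["shape"] / est["rate"]),
                      dispersion = 1 / sqrt(unname(est["shape"])),
                      n_fitted = 2L),
    logistic = hn_family("logistic",
                         location = unname(est["location"]),
                         dispersion = unname(est["scale"]),
                         n_fitted = 2L),
    lognormal = hn_family("lognormal",
                          location = unname(est["meanlog"]),
                          dispersion = unname(est["sdlog"]),
                          n_fitted = 2L)
  )
  attr(fam, "loglik") <- fit$loglik
  attr(fam, "n") <- length(samples)
  fam
}

#' Chi-square goodness of fit with equal-probability bins
#'
#' Assesses how well a parametric family describes a volume sample, binning
#' the observations into cells of equal probability under the candidate
#' distribution so that every cell has the same expected count `n / n_bins`.
#' The statistic is referred to a chi-square distribution with
#' `n_bins - 1 - k` degrees of freedom, where `k` is the number of parameters
#' estimated from the data (carried by the `n_fitted` field of `params`).
#'
#' @param samples Numeric sample; `length(samples) >= 5 * n_bins`.
#' @param params An [hn_family()] object (fitted or fixed).
#' @param n_bins Number of equal-probability cells, `>= 4`. Default 10.
#' @return A tibble of class `hn_gof` with one row: `statistic`, `dof`,
#'   `p_value`, `n_bins`, plus list-columns `bin_edges`, `observed`,
#'   `expected`.
#' @examples
#' set.seed(1)
#' fam <- hn_family("gamma", 3600, 0.11)
#' chi2_gof(hn_sample(fam, 500), fam)
#' @export
chi2_gof <- function(samples, params, n_bins = 10L) {
  stopifnot(inherits(params, "hn_family"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 4L) abort("`n_bins` must be at least 4.")
  n <- length(samples)
  if (n < 5L * n_bins) {
    abort(sprintf("Need at least %d observations for %d bins (5 per bin).",
                  5L * n_bins, n_bins))
  }
  inner <- hn_quantile(params, seq_len(n_bins - 1L) / n_bins)
  edges <- c(-Inf, inner, Inf)
  observed <- as.vector(table(cut(samples, breaks = edges,
                                  include.lowest = TRUE)))
  expected <- rep(n / n_bins, n_bins)
  # merge adjacent cells while any expected count is below 5 (small samples
  # slipping past the precondition via integer division)
  merged <- FALSE
  while (any(expected < 5) && length(expected) > 2L) {
    i <- which.min(expected)
    j <- if (i == 1L) 2L else i - 1L
    keep <- sort(c(i, j))
    observed[keep[1]] <- observed[keep[1]] + observed[keep[2]]
    expected[keep[1]] <- expected[keep[1]] + expected[keep[2]]
    observed <- observed[-keep[2]]
    expected <- expected[-keep[2]]
    edges <- edges[-(keep[2])]
    merged <- TRUE
  }
  if (merged) warn("Expected counts below 5; adjacent bins were merged and the degrees of freedom adjusted.")
  b <- length(expected)
  dof <- max(1L, b - 1L - params$n_fitted)
  statistic <- sum((observed - expected)^2 / expected)
  out <- tibble::tibble(
    statistic = statistic,
    dof = dof,
    p_value = pchisq(statistic, df = dof, lower.tail = FALSE),
    n_bins = b,
    bin_edges = list(edges),
    observed = list(observed),
    expected = list(expected)
  )
  class(out) <- c("hn_gof", class(out))
  out
}

#' Rank candidate families for a volume sample
#'
#' Re-creates the distribution-family search used when choosing a normative
#' family per segmentation tool: each candidate is fitted by maximum
#' likelihood, scored by AIC (primary key, ascending) with the chi-square
#' goodness-of-fit p-value as tie-breaker (descending), and the candidates
#' are returned best-first. Candidates whose fit fails are kept, flagged, and
#' sorted last.
#'
#' @param samples Numeric sample of volumes.
#' @param candidates Character vector of family names; default all three.
#' @param n_bins Bins passed to [chi2_gof()].
#' @return A tibble, one row per candidate, ordered best-first, with columns
#'   `family`, `converged`, `loglik`, `aic`, `gof_statistic`, `gof_p`,
#'   `error` and a list-column `params` of fitted [hn_family()] objects.
#' @examples
#' set.seed(1)
#' rank_families(rgamma(500, shape = 80, rate = 80 / 3600),
#'               c("gamma", "logistic"))
#' @export
rank_families <- function(samples,
                          candidates = c("gamma", "logistic", "lognormal"),
                          n_bins = 10L) {
  if (length(candidates) == 0L) abort("`candidates` must be non-empty.")
  rows <- purrr::map(candidates, function(famname) {
    fit <- tryCatch(mle_fit(samples, famname), error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble::tibble(
        family = famname, converged = FALSE, loglik = NA_real_,
        aic = NA_real_, gof_statistic = NA_real_, gof_p = NA_real_,
        error = conditionMessage(fit), params = list(NULL)
      ))
    }
    gof <- tryCatch(suppressWarnings(chi2_gof(samples, fit, n_bins)),
                    error = function(e) NULL)
    tibble::tibble(
      family = famname, converged = TRUE,
      loglik = attr(fit, "loglik"),
      aic = 2 * 2 - 2 * attr(fit, "loglik"),
      gof_statistic = if (is.null(gof)) NA_real_ else gof$statistic,
      gof_p = if (is.null(gof)) NA_real_ else gof$p_value,
      error = NA_character_, params = list(fit)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!any(out$converged)) {
    abort(paste0("All candidate fits failed:\n", paste0(
      "  - ", out$family, ": ", out$error, collapse = "\n")))
  }
  dplyr::arrange(out, !.data$converged, .data$aic, dplyr::desc(.data$gof_p))
}
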