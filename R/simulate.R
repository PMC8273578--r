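#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical structure that the normative
#' pipeline assumes in real multi-tool volumetric cohorts: hippocampal
#' volumes declining log-linearly with age, Gamma-distributed (FreeSurfer-
#' like) or Logistic-distributed (ACM-Adaboost-like) residual variation,
#' volume-scale mean shifts for the MCI and AD diagnostic groups, head-size
#' variation through a truncated-normal TIV, a positive right-minus-left
#' offset, and optional gross segmentation-failure outliers.
#'
#' Defaults describe an FS-like cognitively normal cohort: ages uniform on
#' 56-90 years, Gamma family with log-link location giving a median volume
#' near 3,600 mm3 at age 74, an age slope of -0.008 per year on the log
#' scale, coefficient of variation 0.11, TIV normal(1,409 ml, 120 ml)
#' truncated at 3 SD, MCI/AD shifts of -349/-658 mm3 (the CN-MCI and CN-AD
#' left-volume differences of a typical validation cohort) and a
#' +100 mm3 right-hemisphere offset.
#'
#' @param seed Integer seed; mandatory, no hidden RNG state is used.
#' @param n_cn,n_mci,n_ad Group sizes (CN/MCI/AD).
#' @param age_min,age_max Age support in years.
#' @param age_dist `"uniform"` or `"normal"` (truncated to the age support).
#' @param age_mean,age_sd Parameters of the truncated-normal option.
#' @param family `"gamma"` or `"logistic"` residual family.
#' @param location_link `"log"` or `"identity"` link for the age-linear
#'   location.
#' @param beta0,beta_age Intercept and per-year slope on the link scale.
#' @param dispersion Constant dispersion (CV for Gamma; scale for Logistic,
#'   on the link scale).
#' @param group_shift Named numeric: volume-scale offsets (mm3) added per
#'   diagnosis; MCI/AD are expected to be non-positive.
#' @param right_offset Volume-scale offset (mm3) of the right over the left
#'   hippocampus.
#' @param tiv_mean_ml,tiv_sd_ml TIV distribution (normal, truncated at 3 SD,
#'   in ml).
#' @param reference_tiv_ml Reference TIV used to de-normalize draws into raw
#'   volumes (the generator draws on the normalized scale so that the
#'   normalization step recovers the generating distribution exactly).
#' @param outlier_rate Fraction of records corrupted by [inject_failures()]
#'   (0 to 0.1).
#' @param outlier_scales Multiplicative factors drawn for corrupted records.
#' @param tool Tool label stamped on the records (`"FS"` or `"AA"`).
#' @return A list of class `hn_gen_config`.
#' @export
generator_config <- function(seed,
                             n_cn = 100, n_mci = 0, n_ad = 0,
                             age_min = 56, age_max = 90,
                             age_dist = c("uniform", "normal"),
                             age_mean = 73, age_sd = 8,
                             family = c("gamma", "logistic"),
                             location_link = NULL,
                             beta0 = log(3600) + 0.008 * 74,
                             beta_age = -0.008,
                             dispersion = 0.11,
                             group_shift = c(CN = 0, MCI = -349, AD = -658),
                             right_offset = 100,
                             tiv_mean_ml = 1409, tiv_sd_ml = 120,
                             reference_tiv_ml = 1409,
                             outlier_rate = 0,
                             outlier_scales = c(0.4, 2.5),
                             tool = "FS") {
  if (missing(seed)) abort("`seed` is mandatory: the generator is fully deterministic given its seed.")
  age_dist <- match.arg(age_dist)
  family <- match.arg(family)
  if (is.null(location_link)) {
    location_link <- if (family == "gamma") "log" else "identity"
  }
  location_link <- match.arg(location_link, c("log", "identity"))
  stopifnot(n_cn >= 0, n_mci >= 0, n_ad >= 0, n_cn + n_mci + n_ad > 0)
  if (age_max <= age_min) abort("`age_max` must exceed `age_min`.")
  if (dispersion <= 0) abort("`dispersion` must be positive.")
  if (outlier_rate < 0 || outlier_rate > 0.1) {
    abort("`outlier_rate` must lie in [0, 0.1].")
  }
  if (tiv_mean_ml <= 0 || tiv_sd_ml < 0) abort("Invalid TIV distribution.")
  if (any(!c("CN", "MCI", "AD") %in% names(group_shift))) {
    abort("`group_shift` must name CN, MCI and AD.")
  }
  if (any(group_shift[c("MCI", "AD")] > 0)) {
    warn("Positive MCI/AD group shifts: diagnostic groups are expected to lose volume.")
  }
  structure(list(
    seed = as.integer(seed), n_cn = n_cn, n_mci = n_mci, n_ad = n_ad,
    age_min = age_min, age_max = age_max, age_dist = age_dist,
    age_mean = age_mean, age_sd = age_sd,
    family = family, location_link = location_link,
    beta0 = beta0, beta_age = beta_age, dispersion = dispersion,
    group_shift = group_shift, right_offset = right_offset,
    tiv_mean_ml = tiv_mean_ml, tiv_sd_ml = tiv_sd_ml,
    reference_tiv_ml = reference_tiv_ml,
    outlier_rate = outlier_rate, outlier_scales = outlier_scales,
    tool = tool
  ), class = "hn_gen_config")
}

# run code with a local, restored RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# inverse-CDF draw of the normalized-scale volume at the generating percentile
volume_from_percentile <- function(u, age, cfg, shift = 0) {
  eta <- cfg$beta0 + cfg$beta_age * age
  if (cfg$family == "gamma") {
    mu <- if (cfg$location_link == "log") exp(eta) else eta
    shape <- 1 / cfg$dispersion^2
    q <- qgamma(u, shape = shape, rate = shape / mu)
  } else {
    q <- qlogis(u, location = eta, scale = cfg$dispersion)
    if (cfg$location_link == "log") q <- exp(q)
  }
  q + shift
}

draw_ages <- function(n, cfg) {
  if (cfg$age_dist == "uniform") {
    runif(n, cfg$age_min, cfg$age_max)
  } else {
    lo <- stats::pnorm(cfg$age_min, cfg$age_mean, cfg$age_sd)
    hi <- stats::pnorm(cfg$age_max, cfg$age_mean, cfg$age_sd)
    stats::qnorm(runif(n, lo, hi), cfg$age_mean, cfg$age_sd)
  }
}

draw_tiv_ml <- function(n, cfg) {
  lo <- stats::pnorm(-3); hi <- stats::pnorm(3)
  cfg$tiv_mean_ml + cfg$tiv_sd_ml * stats::qnorm(runif(n, lo, hi))
}

#' Generate a synthetic cohort
#'
#' Draws a deterministic (seeded) cohort of subject records from the
#' age-conditional generating model described by a [generator_config()].
#' Volumes are drawn on the normalized scale via the inverse CDF at a
#' uniform generating percentile — recorded per subject and hemisphere in
#' the ground-truth sidecar, retrievable with [hn_truth()] — and then
#' de-normalized through each subject's TIV, so that [normalize_cohort()]
#' recovers the generating distribution exactly. When `outlier_rate > 0`,
#' segmentation-failure outliers are injected via [inject_failures()] and
#' marked in the sidecar.
#'
#' @param config A [generator_config()].
#' @return A cohort tibble (`subject_id`, `age`, `sex`, `diagnosis`, `tool`,
#'   `left_hv`, `right_hv`, `tiv_value`, `tiv_unit`) with the truth sidecar
#'   as the `"truth"` attribute.
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 1, n_cn = 20))
#' hn_truth(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "hn_gen_config"))
  cfg <- config
  groups <- rep(c("CN", "MCI", "AD"), c(cfg$n_cn, cfg$n_mci, cfg$n_ad))
  n <- length(groups)
  with_local_seed(cfg$seed, {
    age <- draw_ages(n, cfg)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    tiv_ml <- draw_tiv_ml(n, cfg)
    u_left <- runif(n)
    u_right <- runif(n)
    shift <- unname(cfg$group_shift[groups])
    left_norm <- volume_from_percentile(u_left, age, cfg, shift)
    right_norm <- volume_from_percentile(u_right, age, cfg, shift) +
      cfg$right_offset
    denorm <- (tiv_ml * 1000) / (cfg$reference_tiv_ml * 1000)
    cohort <- tibble::tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = age, sex = sex, diagnosis = groups, tool = cfg$tool,
      left_hv = left_norm * denorm,
      right_hv = right_norm * denorm,
      tiv_value = tiv_ml, tiv_unit = "ml"
    )
    truth <- tibble::tibble(
      subject_id = cohort$subject_id,
      percentile_left = 100 * u_left,
      percentile_right = 100 * u_right,
      group_shift = shift,
      outlier = FALSE
    )
    if (cfg$outlier_rate > 0) {
      inj <- inject_failures(cohort, rate = cfg$outlier_rate,
                             scale_set = cfg$outlier_scales,
                             seed = cfg$seed + 1L)
      cohort <- inj$cohort
      truth$outlier <- inj$mask
    }
    attr(cohort, "truth") <- truth
    cohort
  })
}

#' Inject segmentation-failure outliers
#'
#' Corrupts a random subset of records by multiplying both hippocampal
#' volumes by a gross factor (default 0.4 or 2.5 — under- and
#' over-segmentation), emulating the scans that quality control would
#' discard. The input cohort is not modified; the truth mask identifies the
#' corrupted rows.
#'
#' @param cohort A cohort tibble.
#' @param rate Corruption probability per record, in [0, 0.1].
#' @param scale_set Multiplicative factors sampled per corrupted record.
#' @param seed Integer seed.
#' @return A list: `cohort` (corrupted copy) and `mask` (logical vector).
#' @export
inject_failures <- function(cohort, rate, scale_set = c(0.4, 2.5), seed) {
  stopifnot(is.data.frame(cohort))
  if (rate < 0 || rate > 0.1) abort("`rate` must lie in [0, 0.1].")
  if (missing(seed)) abort("`seed` is mandatory.")
  n <- nrow(cohort)
  with_local_seed(seed, {
    mask <- runif(n) < rate
    out <- cohort
    if (any(mask)) {
      factors <- scale_set[sample.int(length(scale_set), sum(mask),
                                      replace = TRUE)]
      out$left_hv[mask] <- out$left_hv[mask] * factors
      out$right_hv[mask] <- out$right_hv[mask] * factors
    }
    list(cohort = out, mask = mask)
  })
}

#' Generate paired FS-like and AA-like cohorts with correlated abnormality
#'
#' Emulates the same subjects measured by two segmentation tools whose
#' volume scales differ (the AA-like tool reads about 1.4 times higher than
#' the FS-like tool) and whose below-cutoff flags agree only moderately. A
#' shared latent normal deviate plus tool-specific noise produces, through a
#' Gaussian copula, each subject's generating percentile under each tool:
#' `latent_correlation = 1` gives identical percentiles (flag agreement
#' kappa = 1), `0` gives independent tools (kappa near 0), and intermediate
#' values reproduce the moderate-agreement regime seen between real tools.
#'
#' @param config A [generator_config()] describing the FS-like cohort
#'   (ages, groups, TIV, Gamma generating model).
#' @param latent_correlation Correlation of the latent percentiles, in
#'   [0, 1].
#' @param aa_scale Multiplicative volume-scale factor of the AA-like tool
#'   over the FS-like location (default 1.4).
#' @param aa_dispersion Logistic scale (mm3) of the AA-like residuals;
#'   default 330 mm3 (residual SD near 600 mm3).
#' @return A list: `fs` and `aa` cohort tibbles (same subjects, same TIV)
#'   and `truth` (per-subject generating percentiles under each tool).
#' @export
generate_paired_tools <- function(config, latent_correlation = 0.5,
                                  aa_scale = 1.4, aa_dispersion = 330) {
  stopifnot(inherits(config, "hn_gen_config"))
  if (latent_correlation < 0 || latent_correlation > 1) {
    abort("`latent_correlation` must lie in [0, 1].")
  }
  cfg <- config
  groups <- rep(c("CN", "MCI", "AD"), c(cfg$n_cn, cfg$n_mci, cfg$n_ad))
  n <- length(groups)
  with_local_seed(cfg$seed, {
    age <- draw_ages(n, cfg)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    tiv_ml <- draw_tiv_ml(n, cfg)
    shift <- unname(cfg$group_shift[groups])
    z0 <- rnorm(n); e_fs <- rnorm(n); e_aa <- rnorm(n)
    r <- sqrt(latent_correlation)
    u_fs <- stats::pnorm(r * z0 + sqrt(1 - latent_correlation) * e_fs)
    u_aa <- stats::pnorm(r * z0 + sqrt(1 - latent_correlation) * e_aa)
    fs_norm <- volume_from_percentile(u_fs, age, cfg, shift)
    eta <- cfg$beta0 + cfg$beta_age * age
    mu_fs <- if (cfg$location_link == "log") exp(eta) else eta
    aa_norm <- qlogis(u_aa, location = aa_scale * mu_fs,
                      scale = aa_dispersion) + aa_scale * shift
    denorm <- tiv_ml / cfg$reference_tiv_ml
    base <- tibble::tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = age, sex = sex, diagnosis = groups,
      tiv_value = tiv_ml, tiv_unit = "ml"
    )
    make_side <- function(norm_left, tool) {
      dplyr::mutate(base,
                    tool = tool,
                    left_hv = norm_left * denorm,
                    right_hv = (norm_left + cfg$right_offset) * denorm,
                    .after = "diagnosis")
    }
    list(
      fs = make_side(fs_norm, "FS"),
      aa = make_side(aa_norm, "AA"),
      truth = tibble::tibble(
        subject_id = base$subject_id,
        percentile_fs = 100 * u_fs,
        percentile_aa = 100 * u_aa
      )
    )
  })
}
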