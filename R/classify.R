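#' Age-specific percentile of a single volume
#'
#' Translates a subject's (normalized) hippocampal volume into a percentile
#' of the normative population of the same age: 100 times the family CDF at
#' the age-specific location with the model's constant dispersion.
#' Continuous and strictly increasing in the volume.
#'
#' @param model An [fit_normative()] result.
#' @param age Age(s) in years. Ages up to 10 years beyond the fitted range
#'   are accepted with a warning; farther requires `extrapolate = TRUE`.
#' @param volume Volume(s) in mm3 (> 0).
#' @param extrapolate Allow ages far outside the fitted range.
#' @return Percentile(s) in [0, 100].
#' @export
subject_percentile <- function(model, age, volume, extrapolate = FALSE) {
  stopifnot(inherits(model, "hn_model"))
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    abort("`volume` must be finite and strictly positive.")
  }
  if (!extrapolate) check_age(model, age, extrapolate = FALSE, slack = 10)
  near_edge <- age < model$age_range[1] | age > model$age_range[2]
  if (!extrapolate && any(near_edge)) {
    warn(sprintf("Age(s) outside the fitted range %g-%g; percentile is an extrapolation.",
                 model$age_range[1], model$age_range[2]))
  }
  k <- max(length(age), length(volume))
  age <- rep_len(age, k); volume <- rep_len(volume, k)
  loc <- family_at_age(model, age)
  if (model$family == "gamma") {
    shape <- 1 / model$dispersion^2
    100 * pgamma(volume, shape = shape, rate = shape / loc)
  } else {
    100 * plogis(volume, location = loc, scale = model$dispersion)
  }
}

#' Flag a volume as abnormal against norms
#'
#' Applies the abnormality rule — a volume strictly below the age-specific
#' threshold at the decision level (default the 5th percentile) is abnormal;
#' a volume exactly at the threshold is not. The norms source can be a
#' fitted model (any age in range) or a published-anchor
#' [percentile_table()], in which case the age must equal an anchored age:
#' anchors are never interpolated.
#'
#' @param source An `hn_model` or `hn_percentile_table`.
#' @param age Age(s) in years.
#' @param volume Volume(s) in mm3.
#' @param level Decision percentile level in percent (default 5).
#' @param subject_id Optional id(s) carried into the result.
#' @param extrapolate Passed to the model methods.
#' @return A tibble (one row per subject): `subject_id`, `age`, `volume`,
#'   `percentile` (NA when classifying against an anchor table), `level`,
#'   `cutoff_applied`, `abnormal`, `norms_provenance`.
#' @examples
#' norms <- load_published_norms()
#' flag_abnormal(norms$FS_left, age = 56, volume = 3200)
#' @export
flag_abnormal <- function(source, age, volume, level = 5,
                          subject_id = NA_character_, extrapolate = FALSE) {
  UseMethod("flag_abnormal")
}

#' @export
flag_abnormal.hn_model <- function(source, age, volume, level = 5,
                                   subject_id = NA_character_,
                                   extrapolate = FALSE) {
  k <- max(length(age), length(volume))
  age <- rep_len(age, k); volume <- rep_len(volume, k)
  subject_id <- rep_len(subject_id, k)
  # subject_percentile enforces the age policy (10-year slack, then error);
  # the cutoff is then evaluated at the same ages without re-warning
  pct <- subject_percentile(source, age, volume, extrapolate = extrapolate)
  cutoff <- suppressWarnings(
    predict_quantile(source, age, level / 100, extrapolate = TRUE))
  tibble::tibble(
    subject_id = subject_id, age = age, volume = volume,
    percentile = pct, level = level, cutoff_applied = cutoff,
    abnormal = volume < cutoff, norms_provenance = "fitted"
  )
}

#' @export
flag_abnormal.hn_percentile_table <- function(source, age, volume, level = 5,
                                              subject_id = NA_character_,
                                              extrapolate = FALSE) {
  k <- max(length(age), length(volume))
  age <- rep_len(age, k); volume <- rep_len(volume, k)
  subject_id <- rep_len(subject_id, k)
  cutoff <- vapply(age, function(a) threshold_at(source, a, level), numeric(1))
  tibble::tibble(
    subject_id = subject_id, age = age, volume = volume,
    percentile = NA_real_, level = level, cutoff_applied = cutoff,
    abnormal = volume < cutoff,
    norms_provenance = table_provenance(source)
  )
}

#' Mean percentile per diagnostic group
#'
#' Summarises where each diagnostic group of a cohort sits on the normative
#' chart: the mean of [subject_percentile()] within each group (and, when a
#' `hemisphere` column is present, within each hemisphere). In a
#' well-calibrated reference population the cognitively normal group
#' averages near the 50th percentile and atrophic groups drift toward the
#' lower levels.
#'
#' @param data Tibble with age and volume columns plus a grouping column.
#' @param model An [fit_normative()] result.
#' @inheritParams fit_normative
#' @param group_col Grouping column name (default `"diagnosis"`).
#' @param extrapolate Allow ages outside the fitted range.
#' @return A tibble: group (and hemisphere, if present), `n`,
#'   `mean_percentile`. Empty groups are dropped with a warning.
#' @export
group_percentile_summary <- function(data, model, volume_col = "volume",
                                     age_col = "age",
                                     group_col = "diagnosis",
                                     extrapolate = FALSE) {
  stopifnot(is.data.frame(data), inherits(model, "hn_model"))
  if (!group_col %in% names(data)) {
    abort(sprintf("Grouping column '%s' not found.", group_col))
  }
  df <- tibble::tibble(
    group = data[[group_col]],
    hemisphere = if ("hemisphere" %in% names(data)) data$hemisphere else NA,
    age = as.numeric(data[[age_col]]),
    volume = as.numeric(data[[volume_col]])
  )
  bad <- !is.finite(df$age) | !is.finite(df$volume) | is.na(df$group)
  if (any(bad)) {
    warn(sprintf("%d record(s) with missing group, age or volume omitted.", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) abort("No usable records.")
  df$percentile <- subject_percentile(model, df$age, df$volume,
                                      extrapolate = extrapolate)
  keys <- if (all(is.na(df$hemisphere))) "group" else c("group", "hemisphere")
  out <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(keys))),
    n = dplyr::n(),
    mean_percentile = mean(.data$percentile),
    .groups = "drop"
  )
  names(out)[1] <- group_col
  out
}

#' Cohen's kappa for two sets of binary flags
#'
#' Chance-corrected agreement between two binary raters — here, typically the
#' below-cutoff flags produced by two segmentation tools on the same
#' subjects: `kappa = (po - pe) / (1 - pe)` with the usual 2x2 marginal
#' expectation `pe`.
#'
#' @param flags_a,flags_b Logical vectors of equal length (>= 2).
#' @return Kappa in [-1, 1]. With degenerate marginals (`pe = 1`), kappa is
#'   1 when agreement is perfect and an error otherwise.
#' @examples
#' cohens_kappa(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
cohens_kappa <- function(flags_a, flags_b) {
  if (length(flags_a) != length(flags_b)) {
    abort("`flags_a` and `flags_b` must have equal length.")
  }
  keep <- !is.na(flags_a) & !is.na(flags_b)
  a <- as.logical(flags_a[keep]); b <- as.logical(flags_b[keep])
  n <- length(a)
  if (n < 2L) abort("Need at least 2 paired flags.")
  po <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) {
    if (po == 1) return(1)
    abort("Degenerate marginals (pe = 1) with imperfect agreement; kappa undefined.")
  }
  (po - pe) / (1 - pe)
}

#' Diagnostic accuracy metrics against caller-supplied truth
#'
#' Builds the 2x2 confusion table of abnormality flags against an explicit
#' reference standard and reports sensitivity, specificity and predictive
#' values. The reference standard is always supplied by the caller — the
#' package never infers one. When the subjects' percentiles are supplied,
#' the observed percentage below the lower outer level and above the upper
#' outer level are each compared with their nominal expectation by a
#' one-degree-of-freedom chi-square test.
#'
#' @param flags Logical vector: test-positive (abnormal) calls.
#' @param truth Logical vector of the same length: reference-standard
#'   positives.
#' @param percentiles Optional numeric vector of subject percentiles in
#'   [0, 100] for the outer-level discrepancy tests.
#' @param outer_levels Lower/upper outer percentile levels (default
#'   `c(5, 95)`).
#' @return A list of class `hn_diagmetrics`: `counts` (TP/FP/TN/FN tibble),
#'   `metrics` (Se/Sp/PPV/NPV tibble, `NA` where the denominator is zero),
#'   and `tail_tests` (tibble, or `NULL` without percentiles).
#' @examples
#' diagnostic_metrics(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
diagnostic_metrics <- function(flags, truth, percentiles = NULL,
                               outer_levels = c(5, 95)) {
  if (length(flags) != length(truth)) {
    abort("`flags` and `truth` must have equal length.")
  }
  flags <- as.logical(flags); truth <- as.logical(truth)
  if (anyNA(flags) || anyNA(truth)) abort("Flags and truth must be non-missing.")
  tp <- sum(flags & truth); fp <- sum(flags & !truth)
  fn <- sum(!flags & truth); tn <- sum(!flags & !truth)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  metrics <- tibble::tibble(
    metric = c("Se", "Sp", "PPV", "NPV"),
    value = c(ratio(tp, tp + fn), ratio(tn, tn + fp),
              ratio(tp, tp + fp), ratio(tn, tn + fn))
  )
  tail_tests <- NULL
  if (!is.null(percentiles)) {
    if (length(percentiles) != length(flags)) {
      abort("`percentiles` must match `flags` in length.")
    }
    n <- length(percentiles)
    one_tail <- function(count, nominal_pct, label) {
      expected <- n * nominal_pct / 100
      statistic <- (count - expected)^2 / expected +
        ((n - count) - (n - expected))^2 / (n - expected)
      tibble::tibble(
        tail = label, observed = count, observed_pct = 100 * count / n,
        expected_pct = nominal_pct, statistic = statistic,
        p_value = pchisq(statistic, df = 1, lower.tail = FALSE)
      )
    }
    tail_tests <- dplyr::bind_rows(
      one_tail(sum(percentiles < outer_levels[1]), outer_levels[1],
               sprintf("<%gth", outer_levels[1])),
      one_tail(sum(percentiles > outer_levels[2]), 100 - outer_levels[2],
               sprintf(">%gth", outer_levels[2]))
    )
  }
  structure(list(
    counts = tibble::tibble(TP = tp, FP = fp, TN = tn, FN = fn,
                            n = tp + fp + tn + fn),
    metrics = metrics,
    tail_tests = tail_tests
  ), class = "hn_diagmetrics")
}

#' @export
print.hn_diagmetrics <- function(x, ...) {
  cat("<hn_diagmetrics>\n")
  print(x$counts)
  print(x$metrics)
  if (!is.null(x$tail_tests)) print(x$tail_tests)
  invisible(x)
}

#' Single-case report
#'
#' Renders one subject's classification as a structured list (suitable for
#' JSON serialization) plus a plain-text summary, the shape of a clinical
#' volumetric report.
#'
#' @param result One row of a [flag_abnormal()] result.
#' @return A list with elements `report` (list) and `text` (character).
#' @export
single_case_report <- function(result) {
  stopifnot(is.data.frame(result), nrow(result) == 1L)
  report <- as.list(result)
  verdict <- if (result$abnormal) "ABNORMAL (below cutoff)" else "within normal limits"
  text <- paste0(
    sprintf("Subject: %s | age %g years\n", result$subject_id, result$age),
    sprintf("Normalized hippocampal volume: %.0f mm3\n", result$volume),
    if (is.finite(result$percentile)) {
      sprintf("Age-specific percentile: %.1f\n", result$percentile)
    } else "",
    sprintf("Cutoff (level %g): %.0f mm3 [%s norms]\n", result$level,
            result$cutoff_applied, result$norms_provenance),
    sprintf("Classification: %s\n", verdict)
  )
  list(report = report, text = text)
}
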