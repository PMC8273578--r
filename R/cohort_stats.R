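#' Standardize scores against a reference group
#'
#' Cross-cohort harmonization of heterogeneous instruments: each value is
#' expressed as a z-score relative to a reference group (typically the
#' cognitively normal subjects of the same data set), `z = (x - mean) / sd`
#' with the sample (n - 1) standard deviation. For instruments where lower
#' raw scores are better, the sign is flipped so that a higher z is always
#' better.
#'
#' @param values Numeric vector to standardize.
#' @param reference_values Numeric reference sample (`n >= 2`, non-zero SD).
#' @param direction `"higher_better"` (default) or `"lower_better"`.
#' @return A tibble: `raw`, `ref_mean`, `ref_sd`, `z`, `direction`.
#' @examples
#' zscore_to_reference(c(10, 12), rnorm(50, 10, 2))
#' @export
zscore_to_reference <- function(values, reference_values,
                                direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  ref <- reference_values[is.finite(reference_values)]
  if (length(ref) < 2L) abort("Reference group needs at least 2 observations.")
  m <- mean(ref); s <- sd(ref)
  if (s == 0) abort("Reference group has zero standard deviation.")
  z <- (values - m) / s
  if (direction == "lower_better") z <- -z
  tibble::tibble(raw = values, ref_mean = m, ref_sd = s, z = z,
                 direction = direction)
}

#' Per-group descriptive summaries
#'
#' Produces the conventional `mean +/- SD (n = ...)` descriptive layer for a
#' cohort table, one row per group and variable. Missing values are excluded
#' per variable, with the per-variable n reported alongside.
#'
#' @param data A tibble.
#' @param group_col Name of the grouping column (e.g. `"diagnosis"`).
#' @param vars Character vector of numeric columns to summarise; defaults to
#'   every numeric column.
#' @return A tibble: group, `variable`, `n`, `mean`, `sd`, `label` (the
#'   formatted `mean ± sd (n = k)` string; mean omitted when `n = 0`).
#' @examples
#' describe_groups(tibble::tibble(g = "CN", age = c(70, 74)), "g")
#' @export
describe_groups <- function(data, group_col, vars = NULL) {
  stopifnot(is.data.frame(data))
  if (!group_col %in% names(data)) {
    abort(sprintf("Grouping column '%s' not found.", group_col))
  }
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, group_col)
  }
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    abort(sprintf("Variable(s) not found: %s", paste(missing_vars, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(
    data[, c(group_col, vars), drop = FALSE],
    cols = dplyr::all_of(vars), names_to = "variable", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(group_col, "variable")))),
    n = sum(is.finite(.data$value)),
    mean = if (sum(is.finite(.data$value)) > 0) {
      mean(.data$value[is.finite(.data$value)])
    } else NA_real_,
    sd = if (sum(is.finite(.data$value)) > 1) {
      sd(.data$value[is.finite(.data$value)])
    } else NA_real_,
    .groups = "drop"
  )
  dplyr::mutate(out, label = dplyr::case_when(
    .data$n == 0 ~ sprintf("(n = 0)"),
    is.na(.data$sd) ~ sprintf("%.2f (n = %d)", .data$mean, .data$n),
    TRUE ~ sprintf("%.2f ± %.2f (n = %d)", .data$mean, .data$sd, .data$n)
  ))
}
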