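#' Head-size normalization settings
#'
#' Hippocampal volumes scale with head size; the package removes that effect
#' with the proportional method, rescaling each volume to what it would be in
#' a head of fixed reference intracranial volume. The reference defaults to
#' 1,409 ml, the same value for FreeSurfer eTIV and SPM-derived TIV sources.
#'
#' @param reference_tiv_ml Reference total intracranial volume in ml (> 0).
#' @return A list of class `hn_norm_config`.
#' @export
normalization_config <- function(reference_tiv_ml = 1409) {
  if (!is.numeric(reference_tiv_ml) || length(reference_tiv_ml) != 1L ||
      !is.finite(reference_tiv_ml) || reference_tiv_ml <= 0) {
    abort("`reference_tiv_ml` must be a single positive number.")
  }
  structure(list(reference_tiv_ml = reference_tiv_ml),
            class = "hn_norm_config")
}

# plausible adult TIV window, in ml
TIV_PLAUSIBLE_ML <- c(800, 2200)

tiv_to_mm3 <- function(tiv_value, tiv_unit) {
  if (!all(tiv_unit %in% c("ml", "mm3"))) {
    abort("`tiv_unit` must be 'ml' or 'mm3'.")
  }
  ifelse(tiv_unit == "ml", tiv_value * 1000, tiv_value)
}

#' Normalize a hippocampal volume to the reference head size
#'
#' Computes `hv / tiv * reference_tiv`, with the TIV first converted to mm3
#' from its declared unit. At `tiv` equal to the reference the volume is
#' returned unchanged; the result scales linearly in `hv` and inversely in
#' `tiv`.
#'
#' @param hv Hippocampal volume in mm3 (> 0). Vectorized.
#' @param tiv_value Total intracranial volume (> 0), in `tiv_unit`.
#' @param tiv_unit `"ml"` or `"mm3"`; no auto-detection is ever attempted.
#' @param config A [normalization_config()].
#' @return Normalized volume(s) in mm3. A warning is raised (computation
#'   proceeds) when the TIV falls outside the plausible 800-2,200 ml window.
#' @examples
#' normalize_hv(3000, 1409, "ml")   # reference head: unchanged
#' normalize_hv(3000, 2818, "ml")   # doubled head size: halved
#' @export
normalize_hv <- function(hv, tiv_value, tiv_unit = c("ml", "mm3"),
                         config = normalization_config()) {
  tiv_unit <- match.arg(tiv_unit)
  stopifnot(inherits(config, "hn_norm_config"))
  if (any(!is.finite(hv)) || any(hv <= 0)) {
    abort("`hv` must be finite and strictly positive.")
  }
  if (any(!is.finite(tiv_value)) || any(tiv_value <= 0)) {
    abort("`tiv_value` must be finite and strictly positive.")
  }
  tiv_mm3 <- tiv_to_mm3(tiv_value, tiv_unit)
  tiv_ml <- tiv_mm3 / 1000
  if (any(tiv_ml < TIV_PLAUSIBLE_ML[1] | tiv_ml > TIV_PLAUSIBLE_ML[2])) {
    warn(sprintf(
      "TIV outside the plausible %g-%g ml range; normalization proceeds but the record should be reviewed.",
      TIV_PLAUSIBLE_ML[1], TIV_PLAUSIBLE_ML[2]))
  }
  # ratio first: at tiv == reference the factor is exactly 1
  hv * ((config$reference_tiv_ml * 1000) / tiv_mm3)
}

#' Normalize every record of a cohort
#'
#' Attaches `left_hv_norm` / `right_hv_norm` columns computed with
#' [normalize_hv()] to a cohort tibble, preserving row order and the raw
#' volumes. Records lacking a usable TIV are excluded from the returned
#' tibble and reported via [hn_skipped()].
#'
#' @param cohort A cohort tibble as returned by [read_cohort()] or
#'   [generate_cohort()]: needs `left_hv`, `right_hv`, `tiv_value`,
#'   `tiv_unit` columns.
#' @param config A [normalization_config()].
#' @return The cohort tibble with normalized-volume columns added; skipped
#'   records (missing/non-positive TIV) are attached as the `"skipped"`
#'   attribute.
#' @export
normalize_cohort <- function(cohort, config = normalization_config()) {
  stopifnot(is.data.frame(cohort))
  cohort <- tibble::as_tibble(cohort)
  required <- c("left_hv", "right_hv", "tiv_value", "tiv_unit")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("Cohort is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cohort) == 0L) {
    out <- dplyr::mutate(cohort, left_hv_norm = numeric(0),
                         right_hv_norm = numeric(0))
    attr(out, "skipped") <- cohort
    return(out)
  }
  usable <- is.finite(cohort$tiv_value) & cohort$tiv_value > 0 &
    cohort$tiv_unit %in% c("ml", "mm3")
  skipped <- cohort[!usable, , drop = FALSE]
  if (nrow(skipped) > 0) {
    warn(sprintf("%d record(s) lack a usable TIV and were excluded from normalization.",
                 nrow(skipped)))
  }
  kept <- cohort[usable, , drop = FALSE]
  tiv_mm3 <- tiv_to_mm3(kept$tiv_value, kept$tiv_unit)
  scale <- (config$reference_tiv_ml * 1000) / tiv_mm3
  out <- dplyr::mutate(kept,
                       left_hv_norm = .data$left_hv * .env$scale,
                       right_hv_norm = .data$right_hv * .env$scale)
  attr(out, "skipped") <- skipped
  out
}

#' Records set aside by a pipeline step
#'
#' `hn_skipped()` retrieves records excluded by [normalize_cohort()];
#' `hn_rejected()` retrieves rows rejected by [read_cohort()] together with
#' the rejection reason; `hn_truth()` retrieves the generating ground truth
#' attached by [generate_cohort()].
#'
#' @param x A tibble returned by the corresponding pipeline function.
#' @return A tibble (possibly empty), or `NULL` when no such attribute
#'   exists.
#' @export
hn_skipped <- function(x) attr(x, "skipped", exact = TRUE)

#' @rdname hn_skipped
#' @export
hn_rejected <- function(x) attr(x, "rejected", exact = TRUE)

#' @rdname hn_skipped
#' @export
hn_truth <- function(x) attr(x, "truth", exact = TRUE)
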