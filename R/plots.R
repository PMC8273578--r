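#' Percentile chart of a fitted normative model
#'
#' Draws the age-specific percentile curves of a fitted model, the usual
#' growth-chart presentation of volumetric norms.
#'
#' @param object An [fit_normative()] result.
#' @param levels Percentile levels to draw.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.hn_model <- function(object, levels = c(5, 10, 25, 50, 75, 90, 95),
                              ...) {
  ages <- seq(object$age_range[1], object$age_range[2], length.out = 100)
  df <- tidyr::expand_grid(age = ages, level = levels)
  df$threshold <- predict_quantile(object, df$age, df$level / 100)
  df$level <- factor(df$level, levels = sort(levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$threshold,
                                   colour = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (years)", y = "Normalized volume (mm³)",
                  colour = "Percentile",
                  title = sprintf("%s-family normative percentile curves",
                                  object$family)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.hn_model
#' @export
autoplot.hn_percentile_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$level <- factor(df$level, levels = sort(unique(df$level)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$threshold,
                                   colour = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Age (years)", y = "Volume threshold (mm³)",
                  colour = "Percentile",
                  title = sprintf("%s %s hippocampus (%s norms)",
                                  df$tool[1], df$hemisphere[1],
                                  table_provenance(object))) +
    ggplot2::theme_minimal()
}

#' Cohort scatter over the normative chart
#'
#' Overlays a cohort's (age, volume) points, coloured by diagnosis, on the
#' percentile curves of a fitted model — the standard validation view for
#' norms applied to an external cohort.
#'
#' @param data Tibble with age and volume columns and a diagnosis column.
#' @param model An [fit_normative()] result.
#' @inheritParams fit_normative
#' @param group_col Colouring column (default `"diagnosis"`).
#' @param levels Percentile levels to draw.
#' @return A ggplot object.
#' @export
plot_cohort_percentiles <- function(data, model, volume_col = "volume",
                                    age_col = "age",
                                    group_col = "diagnosis",
                                    levels = c(5, 10, 25, 50, 75, 90, 95)) {
  p <- autoplot(model, levels = levels)
  pts <- tibble::tibble(
    age = as.numeric(data[[age_col]]),
    volume = as.numeric(data[[volume_col]]),
    group = if (group_col %in% names(data)) data[[group_col]] else "cohort"
  )
  p + ggplot2::geom_point(
    data = pts,
    ggplot2::aes(x = .data$age, y = .data$volume, shape = .data$group),
    inherit.aes = FALSE, alpha = 0.6) +
    ggplot2::labs(shape = group_col)
}
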