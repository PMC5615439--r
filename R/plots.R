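#' Plot days of monitoring needed per outcome
#'
#' Bar chart of the Spearman-Brown days-needed recommendation for each
#' outcome, annotated with the single-day ICC. Outcomes whose
#' extrapolation exceeds the observed monitoring window are shaded.
#'
#' @param object A `reliability_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reliability_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$days_needed), , drop = FALSE]
  df$outcome <- stats::reorder(df$outcome, df$days_needed)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$outcome, y = .data$days_needed,
    fill = .data$beyond_observed
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("ICC %.2f", .data$icc_single_day)),
      hjust = -0.1, size = 3
    ) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "grey70"),
      labels = c(`FALSE` = "within window", `TRUE` = "extrapolated"),
      name = NULL
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = sprintf("Days needed for ICC > %.2f",
                  attr(object, "target_icc") %||% 0.80)
    ) +
    ggplot2::theme_minimal()
}

#' Plot day-of-week adjusted means
#'
#' @param object A `dow_effects` object from [day_of_week_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dow_effects <- function(object, ...) {
  df <- object$adjusted_means
  df$day_of_week <- factor(df$day_of_week, levels = .day_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day_of_week, y = .data$adjusted_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::labs(x = NULL, y = object$outcome) +
    ggplot2::theme_minimal()
}

#' Plot the energy-balance component summary
#'
#' @param balance Output of [energy_balance_summary()].
#' @return A stacked bar chart of component kcal by side.
#' @export
plot_energy_balance <- function(balance) {
  df <- balance[balance$component != "total", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$side, y = .data$kcal_mean, fill = .data$component
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "kcal/day", fill = NULL) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
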