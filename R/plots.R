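# ggplot2 views of the result tables. These are working plots for
# surveillance review, not publication styling.

#' Plot cumulative coverage curves
#'
#' One line per cohort, faceted by series, on the months-from-reference
#' axis with Wilson confidence ribbons.
#'
#' @param object An `sbip_coverage` tibble from [coverage_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sbip_coverage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$months_from_reference, y = 100 * .data$proportion,
    colour = .data$cohort_id, fill = .data$cohort_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * .data$ci_low,
                                      ymax = 100 * .data$ci_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~antigen_group) +
    ggplot2::labs(x = "Months from end of grade year",
                  y = "Cumulative coverage (%)",
                  colour = "Cohort", fill = "Cohort") +
    ggplot2::theme_minimal()
}

#' Plot coverage-difference curves
#'
#' Percentage-point differences from the prepandemic counterfactual, one
#' line per pandemic cohort, faceted by series, with a zero reference line.
#'
#' @param object An `sbip_coverage_diff` tibble from
#'   [coverage_differences()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sbip_coverage_diff <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$months_from_reference, y = .data$diff_pp,
    colour = .data$cohort_id, fill = .data$cohort_id)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~antigen_group) +
    ggplot2::labs(x = "Months from end of grade year",
                  y = "Coverage difference vs prepandemic (pp)",
                  colour = "Cohort", fill = "Cohort") +
    ggplot2::theme_minimal()
}

#' Plot administration volume by period
#'
#' Stacked routine/catch-up dose counts per school-year and summer period,
#' faceted by cohort.
#'
#' @param object An `sbip_volume` tibble from [volume_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sbip_volume <- function(object, ...) {
  long <- object %>%
    tidyr::pivot_longer(c("routine_count", "catchup_count"),
                        names_to = "class", values_to = "doses") %>%
    mutate(class = ifelse(.data$class == "routine_count", "routine",
                          "catch-up"),
           period_label = paste(.data$period_years, .data$period))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period_label, y = .data$doses,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(antigen_group ~ cohort_id) +
    ggplot2::labs(x = NULL, y = "Doses delivered", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname autoplot.sbip_coverage
#' @param coverage An `sbip_coverage` tibble.
#' @export
plot_coverage <- function(coverage, ...) autoplot.sbip_coverage(coverage, ...)

#' @rdname autoplot.sbip_coverage_diff
#' @param differences An `sbip_coverage_diff` tibble.
#' @export
plot_coverage_difference <- function(differences, ...) {
  autoplot.sbip_coverage_diff(differences, ...)
}

#' @rdname autoplot.sbip_volume
#' @param volumes An `sbip_volume` tibble.
#' @export
plot_volume <- function(volumes, ...) autoplot.sbip_volume(volumes, ...)
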