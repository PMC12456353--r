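# Cumulative immunization deficits and projected catch-up time: the
# counterfactual expected number vaccinated applies the prepandemic cohort's
# maximum observed coverage to each pandemic cohort's size; the deficit is
# observed minus expected (negative = shortfall); time to clear divides the
# shortfall by observed annual catch-up uptake (minimum time from the
# maximum annual uptake, average time from the mean).

#' Counterfactual expected number vaccinated
#'
#' Applies the prepandemic cohort's maximum observed coverage proportion to
#' each pandemic cohort's size, sums as reals, and rounds half-up to an
#' integer once at the end.
#'
#' @param prepandemic_coverage Coverage proportion in `[0, 1]`.
#' @param pandemic_sizes Integer vector of pandemic cohort sizes.
#' @return Integer expected count.
#' @export
expected_vaccinated <- function(prepandemic_coverage, pandemic_sizes) {
  stopifnot(prepandemic_coverage >= 0, prepandemic_coverage <= 1,
            all(pandemic_sizes >= 0))
  as.integer(floor(sum(prepandemic_coverage * as.numeric(pandemic_sizes)) + 0.5))
}

#' Cumulative deficit
#'
#' @param expected,observed Non-negative counts.
#' @return `observed - expected` (negative when coverage fell short).
#' @export
cumulative_deficit <- function(expected, observed) {
  stopifnot(all(expected >= 0), all(observed >= 0))
  observed - expected
}

#' Years of catch-up effort to clear a deficit
#'
#' @param deficit Signed count (negative = shortfall).
#' @param annual_uptake Catch-up doses per year; must be positive when there
#'   is a shortfall to clear.
#' @return `abs(deficit) / annual_uptake` years, or 0 when `deficit >= 0`.
#' @export
time_to_clear <- function(deficit, annual_uptake) {
  if (deficit >= 0) return(0)
  if (annual_uptake <= 0) {
    abort("Cannot project time to clear a shortfall with non-positive annual uptake",
          class = "sbip_undefined_horizon")
  }
  abs(deficit) / annual_uptake
}

#' Format projected years like a summary table
#'
#' Two decimals below one year, one decimal otherwise.
#'
#' @param years Numeric vector of years.
#' @return Character vector.
#' @export
format_years <- function(years) {
  ifelse(years < 1, sprintf("%.2f", years), sprintf("%.1f", years))
}

#' Deficit report for every grade program and series
#'
#' One row per (grade program, series): the prepandemic cohort's maximum
#' observed coverage is applied to the pandemic cohort sizes to get the
#' expected count; the observed count sums each pandemic cohort's covered
#' members at the study end; annual catch-up uptake windows (July-June) give
#' the minimum (from maximum annual uptake) and average (from mean annual
#' uptake) years to clear any shortfall.
#'
#' @param coverage Coverage tibble from [coverage_curves()].
#' @param volumes Volume tibble from [volume_table()].
#' @param cohorts The `cohort_set`.
#' @param series_registry Series tibble.
#' @return An `sbip_deficits` tibble: `program_grade`, `antigen_group`,
#'   `series_label`, `expected_vaccinated`, `observed_vaccinated`,
#'   `cumulative_deficit`, `max_annual_uptake`, `avg_annual_uptake`,
#'   `min_years_to_clear`, `avg_years_to_clear`.
#' @export
deficit_table <- function(coverage, volumes, cohorts, series_registry) {
  specs <- cohorts$specs
  out <- list()
  for (pg in sort(unique(series_registry$grade))) {
    pre <- specs[specs$program_grade == pg & specs$role == "prepandemic", ]
    pans <- specs[specs$program_grade == pg & specs$role == "pandemic", ]
    if (nrow(pre) != 1) {
      abort(sprintf("Grade %d program needs exactly one prepandemic cohort", pg),
            class = "sbip_config_error")
    }
    sers <- series_registry[series_registry$grade == pg, ]
    for (j in seq_len(nrow(sers))) {
      sr <- sers[j, ]
      pre_cov <- coverage[coverage$cohort_id == pre$cohort_id &
                          coverage$antigen_group == sr$antigen_group, ]
      if (nrow(pre_cov) == 0) next
      pre_max <- max(pre_cov$proportion)

      observed <- 0L; sizes <- integer(0)
      for (cid in pans$cohort_id) {
        pc <- coverage[coverage$cohort_id == cid &
                       coverage$antigen_group == sr$antigen_group, ]
        if (nrow(pc) == 0) next
        last <- pc[which.max(ym_index(pc$calendar_month)), ]
        observed <- observed + last$n_covered
        sizes <- c(sizes, last$n_total)
      }
      expected <- expected_vaccinated(pre_max, sizes)
      deficit <- cumulative_deficit(expected, observed)
      uptake <- annual_catchup_uptake(volumes, cohorts, pg, sr$antigen_group,
                                      observation_end = pre$observation_end)
      out[[length(out) + 1]] <- tibble(
        program_grade = pg, antigen_group = sr$antigen_group,
        series_label = sr$series_label,
        expected_vaccinated = expected, observed_vaccinated = observed,
        cumulative_deficit = deficit,
        max_annual_uptake = uptake$max_annual,
        avg_annual_uptake = uptake$mean_annual,
        min_years_to_clear = if (uptake$max_annual > 0 || deficit >= 0)
          time_to_clear(deficit, uptake$max_annual) else NA_real_,
        avg_years_to_clear = if (uptake$mean_annual > 0 || deficit >= 0)
          time_to_clear(deficit, uptake$mean_annual) else NA_real_
      )
    }
  }
  structure(bind_rows(out),
            class = c("sbip_deficits", "tbl_df", "tbl", "data.frame"))
}

#' @describeIn deficit_table `tidy()` returns the report as a plain tibble.
#' @param x An `sbip_deficits` table.
#' @param ... Unused.
#' @method tidy sbip_deficits
#' @export
tidy.sbip_deficits <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @describeIn deficit_table `glance()` returns one-row study totals.
#' @method glance sbip_deficits
#' @export
glance.sbip_deficits <- function(x, ...) {
  tibble(
    n_series = nrow(x),
    total_expected = sum(x$expected_vaccinated),
    total_observed = sum(x$observed_vaccinated),
    total_deficit = sum(x$cumulative_deficit),
    worst_avg_years = max(x$avg_years_to_clear, na.rm = TRUE)
  )
}

#' Markdown rendering of a deficit report
#'
#' @param x An `sbip_deficits` table.
#' @return A character scalar of markdown table lines.
#' @export
deficit_report_markdown <- function(x) {
  hdr <- paste(
    "| Grade | Vaccine | Expected | Observed | Cumulative deficit |",
    "Minimum (years) | Average (years) |")
  sep <- "|---|---|---|---|---|---|---|"
  rows <- sprintf(
    "| %d | %s | %s | %s | %s | %s | %s |",
    x$program_grade, x$series_label,
    format(x$expected_vaccinated, big.mark = ","),
    format(x$observed_vaccinated, big.mark = ","),
    format(x$cumulative_deficit, big.mark = ","),
    format_years(x$min_years_to_clear), format_years(x$avg_years_to_clear))
  paste(c(hdr, sep, rows), collapse = "\n")
}
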