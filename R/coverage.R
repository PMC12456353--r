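# Monthly cumulative coverage with binomial confidence intervals, and
# month-aligned coverage differences against the prepandemic counterfactual.
#
# Single proportions use the Wilson score interval (well-behaved at the
# 0/1 coverage levels common here); differences of two independent
# proportions use the Wald (normal) interval on the difference, in
# percentage points.

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes (vectorised), `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `low` and `high`; the interval always
#'   contains `k/n`, is exactly 0 at its lower bound when `k = 0`, and
#'   exactly 1 at its upper bound when `k = n`.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  if (any(n < 1)) abort("`n` must be >= 1 (empty denominators are an error)")
  if (any(k < 0 | k > n)) abort("`k` must satisfy 0 <= k <= n")
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  low <- pmax(0, centre - half)
  high <- pmin(1, centre + half)
  low[k == 0] <- 0
  high[k == n] <- 1
  tibble(low = low, high = high)
}

#' Signed whole months from a cohort's reference month
#'
#' The alignment axis for counterfactual comparisons: whole months elapsed
#' since July of the cohort's grade-year end (negative for Grade 1
#' pre-reference months, which are tracked from school entry in September).
#'
#' @param spec A one-row cohort spec (needs a `reference_month` column).
#' @param calendar_month `"YYYY-MM"` month key(s).
#' @return Integer vector of signed month offsets.
#' @export
months_from_reference <- function(spec, calendar_month) {
  ym_index(calendar_month) - ym_index(spec$reference_month)
}

# month index (ym_index scale) at which each member first reaches
# `threshold` doses of the antigen group; NA if never within the dose data
covered_month_index <- function(member_ids, doses, antigen_group, threshold) {
  d <- doses %>%
    filter(.data$antigen_group == !!antigen_group,
           .data$person_id %in% member_ids)
  if (nrow(d) == 0) {
    return(setNames(rep(NA_integer_, length(member_ids)), member_ids))
  }
  d <- d %>%
    mutate(m_idx = ym_index(date_to_ym(.data$administration_date))) %>%
    arrange(.data$person_id, .data$m_idx) %>%
    group_by(.data$person_id) %>%
    mutate(dose_no = row_number()) %>%
    filter(.data$dose_no == !!threshold) %>%
    ungroup()
  out <- setNames(rep(NA_integer_, length(member_ids)), member_ids)
  out[d$person_id] <- d$m_idx
  out
}

#' Monthly cumulative coverage for one cohort and series
#'
#' For each calendar month `t` in `months`, counts the cohort members with
#' at least `threshold` recorded doses of the series' antigen group dated on
#' or before the last day of `t` (closed month end), with the cohort size as
#' a fixed closed-cohort denominator, and attaches a Wilson confidence
#' interval.
#'
#' @param members Character vector of member person ids, or a tibble with a
#'   `person_id` column (e.g. a filtered `tidy(cohort_set)`).
#' @param doses Dose tibble.
#' @param spec One-row cohort spec (for the cohort id and reference month).
#' @param series One-row series tibble from [series_spec()]; the dose
#'   threshold is resolved for this cohort's school year via
#'   [required_doses()].
#' @param months Character vector of `"YYYY-MM"` months; defaults to the
#'   spec's `coverage_start` through `observation_end`.
#' @param level Confidence level for the Wilson interval.
#' @return A tibble of coverage points: `cohort_id`, `antigen_group`,
#'   `dose_threshold`, `calendar_month`, `months_from_reference`,
#'   `n_covered`, `n_total`, `proportion`, `ci_low`, `ci_high`.
#' @export
cumulative_coverage <- function(members, doses, spec, series,
                                months = NULL, level = 0.95) {
  if (is.data.frame(members)) members <- members$person_id
  n_total <- length(members)
  if (n_total == 0) {
    abort(sprintf("Cohort %s is empty: coverage is undefined", spec$cohort_id))
  }
  months <- months %||% ym_seq(spec$coverage_start, spec$observation_end)
  threshold <- required_doses(series, spec$school_year)
  cm <- covered_month_index(members, doses, series$antigen_group, threshold)
  m_idx <- ym_index(months)
  n_covered <- vapply(m_idx, function(t) sum(!is.na(cm) & cm <= t), integer(1))
  ci <- binomial_ci(n_covered, n_total, level)
  tibble(
    cohort_id = spec$cohort_id, antigen_group = series$antigen_group,
    dose_threshold = threshold, calendar_month = months,
    months_from_reference = months_from_reference(spec, months),
    n_covered = n_covered, n_total = n_total,
    proportion = n_covered / n_total, ci_low = ci$low, ci_high = ci$high
  )
}

#' Coverage for every cohort and tracked series
#'
#' Convenience wrapper running [cumulative_coverage()] over all cohorts of a
#' `cohort_set` and all series of a registry whose grade matches the
#' cohort's program grade.
#'
#' @param cohorts A `cohort_set` from [build_cohorts()].
#' @param doses Dose tibble.
#' @param series_registry Series tibble, e.g. [default_series_registry()].
#' @param level Confidence level.
#' @return A coverage tibble (class `sbip_coverage`) over all cohort/series.
#' @export
coverage_curves <- function(cohorts, doses, series_registry, level = 0.95) {
  out <- list()
  for (i in seq_len(nrow(cohorts$specs))) {
    sp <- cohorts$specs[i, ]
    ids <- cohorts$members$person_id[cohorts$members$cohort_id == sp$cohort_id]
    if (length(ids) == 0) next
    sers <- series_registry[series_registry$grade == sp$program_grade, ]
    for (j in seq_len(nrow(sers))) {
      out[[length(out) + 1]] <- cumulative_coverage(ids, doses, sp, sers[j, ],
                                                    level = level)
    }
  }
  structure(bind_rows(out), class = c("sbip_coverage", "tbl_df", "tbl",
                                      "data.frame"))
}

#' Month-aligned coverage difference against the counterfactual
#'
#' Joins a pandemic cohort's coverage points to the prepandemic cohort's at
#' the same `months_from_reference` and reports the difference in percentage
#' points (pandemic minus prepandemic), with a Wald confidence interval from
#' the standard-error combination of the two independent binomial
#' proportions.
#'
#' @param pandemic,prepandemic Coverage tibbles from [cumulative_coverage()]
#'   for a single cohort/series each.
#' @param level Confidence level.
#' @return A tibble: `cohort_id`, `antigen_group`, `months_from_reference`,
#'   `calendar_month`, `diff_pp`, `ci_low`, `ci_high` (percentage points).
#' @export
coverage_difference <- function(pandemic, prepandemic, level = 0.95) {
  shared <- intersect(pandemic$months_from_reference,
                      prepandemic$months_from_reference)
  if (length(shared) == 0) {
    abort("No overlapping months_from_reference between the two series")
  }
  a <- pandemic[match(shared, pandemic$months_from_reference), ]
  b <- prepandemic[match(shared, prepandemic$months_from_reference), ]
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(a$proportion * (1 - a$proportion) / a$n_total +
             b$proportion * (1 - b$proportion) / b$n_total)
  diff <- a$proportion - b$proportion
  tibble(
    cohort_id = a$cohort_id, antigen_group = a$antigen_group,
    months_from_reference = shared, calendar_month = a$calendar_month,
    diff_pp = 100 * diff,
    ci_low = 100 * (diff - z * se), ci_high = 100 * (diff + z * se)
  )
}

#' All pandemic-vs-prepandemic coverage differences
#'
#' Runs [coverage_difference()] for every pandemic cohort and series of a
#' coverage table, using the prepandemic cohort of the same program grade as
#' the counterfactual.
#'
#' @param coverage A coverage tibble from [coverage_curves()].
#' @param cohorts The `cohort_set` the coverage was computed from.
#' @param level Confidence level.
#' @return A difference tibble (class `sbip_coverage_diff`).
#' @export
coverage_differences <- function(coverage, cohorts, level = 0.95) {
  specs <- cohorts$specs
  out <- list()
  for (pg in unique(specs$program_grade)) {
    pre <- specs[specs$program_grade == pg & specs$role == "prepandemic", ]
    if (nrow(pre) == 0) {
      abort(sprintf("No prepandemic cohort configured for grade %d program", pg))
    }
    pans <- specs[specs$program_grade == pg & specs$role == "pandemic", ]
    for (ag in unique(coverage$antigen_group[
        coverage$cohort_id %in% c(pre$cohort_id, pans$cohort_id)])) {
      pre_cov <- coverage[coverage$cohort_id == pre$cohort_id &
                          coverage$antigen_group == ag, ]
      if (nrow(pre_cov) == 0) next
      for (cid in pans$cohort_id) {
        pan_cov <- coverage[coverage$cohort_id == cid &
                            coverage$antigen_group == ag, ]
        if (nrow(pan_cov) == 0) next
        out[[length(out) + 1]] <- coverage_difference(pan_cov, pre_cov, level)
      }
    }
  }
  structure(bind_rows(out), class = c("sbip_coverage_diff", "tbl_df", "tbl",
                                      "data.frame"))
}
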