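# Dose administration volume: classify each dose as routine (delivered
# during the cohort's scheduled school year, September 1 to June 30) or
# catch-up (delivered after June 30 of the grade year), and collapse monthly
# counts into school-year (September-June) and summer (July-August) periods.
# Doses predating the grade year are counted under neither (for Grade 1
# these are preschool doses: they count toward coverage but not toward
# program-era delivery volume).

#' Classify a dose as routine or catch-up
#'
#' @param administration_date `Date` vector of dose dates.
#' @param spec One-row cohort spec (for the grade year).
#' @return Character vector: `"routine"` for doses within September 1 to
#'   June 30 of the grade year, `"catchup"` after June 30, `NA` before the
#'   grade year (unclassified).
#' @export
classify_dose <- function(administration_date, spec) {
  b <- school_year_bounds(spec$school_year)
  june30 <- as.Date(sprintf("%d-06-30",
                            school_year_start_year(spec$school_year) + 1L))
  out <- rep(NA_character_, length(administration_date))
  out[administration_date >= b$start & administration_date <= june30] <- "routine"
  out[administration_date > june30] <- "catchup"
  out
}

# period label for a month: "YYYY-YYYY school_year" (Sept-June) or
# "YYYY summer" (July-August)
period_of_month <- function(ym) {
  y <- as.integer(substr(ym, 1, 4))
  m <- as.integer(substr(ym, 6, 7))
  label <- character(length(m)); span <- character(length(m))
  summer <- m %in% c(7L, 8L)
  label[summer] <- "summer"; label[!summer] <- "school_year"
  span[summer] <- as.character(y[summer])
  fall <- !summer & m >= 9L
  span[fall] <- sprintf("%d-%d", y[fall], y[fall] + 1L)
  spring <- !summer & m < 7L
  span[spring] <- sprintf("%d-%d", y[spring] - 1L, y[spring])
  tibble(period = label, period_years = span)
}

#' Routine and catch-up dose volumes by period
#'
#' Counts every classified dose of the series' antigen group delivered to
#' cohort members, exactly once, into school-year (September-June) and
#' summer (July-August) periods partitioning the study range. Counts are
#' dose counts, not person counts. Doses predating the grade year are
#' excluded with a log message.
#'
#' @param members Character vector of member ids (or tibble with
#'   `person_id`).
#' @param doses Dose tibble.
#' @param spec One-row cohort spec.
#' @param series One-row series tibble.
#' @param study_range `c(first, last)` calendar months (`"YYYY-MM"`);
#'   defaults to the grade-year start through the spec's observation end.
#' @return A tibble: `cohort_id`, `antigen_group`, `period`, `period_years`,
#'   `routine_count`, `catchup_count` — one row per period in the range,
#'   zero-filled.
#' @export
period_volumes <- function(members, doses, spec, series, study_range = NULL) {
  if (is.data.frame(members)) members <- members$person_id
  y1 <- school_year_start_year(spec$school_year)
  study_range <- study_range %||% c(sprintf("%d-09", y1), spec$observation_end)
  months <- ym_seq(study_range[1], study_range[2])

  d <- doses %>%
    filter(.data$antigen_group == series$antigen_group,
           .data$person_id %in% members) %>%
    mutate(ym = date_to_ym(.data$administration_date),
           class = classify_dose(.data$administration_date, spec))
  n_pre <- sum(is.na(d$class))
  if (n_pre > 0) {
    inform(sprintf(
      "%s/%s: %d dose(s) predate the grade year; excluded from volume counts",
      spec$cohort_id, series$antigen_group, n_pre))
  }
  d <- filter(d, !is.na(.data$class), .data$ym %in% months)

  grid <- dplyr::bind_cols(tibble(ym = months), period_of_month(months)) %>%
    distinct(.data$period, .data$period_years)
  counted <- d %>%
    dplyr::bind_cols(period_of_month(d$ym)) %>%
    count(.data$period, .data$period_years, .data$class) %>%
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (col in c("routine", "catchup")) {
    if (!col %in% names(counted)) {
      counted[[col]] <- rep(0L, nrow(counted))
    }
  }
  grid %>%
    left_join(counted, by = c("period", "period_years")) %>%
    mutate(cohort_id = spec$cohort_id, antigen_group = series$antigen_group,
           routine_count = dplyr::coalesce(.data$routine, 0L),
           catchup_count = dplyr::coalesce(.data$catchup, 0L)) %>%
    select("cohort_id", "antigen_group", "period", "period_years",
           "routine_count", "catchup_count")
}

#' Volumes for every cohort and tracked series
#'
#' @param cohorts A `cohort_set`.
#' @param doses Dose tibble.
#' @param series_registry Series tibble.
#' @return A volume tibble (class `sbip_volume`) over all cohort/series.
#' @export
volume_table <- function(cohorts, doses, series_registry) {
  out <- list()
  for (i in seq_len(nrow(cohorts$specs))) {
    sp <- cohorts$specs[i, ]
    ids <- cohorts$members$person_id[cohorts$members$cohort_id == sp$cohort_id]
    if (length(ids) == 0) next
    sers <- series_registry[series_registry$grade == sp$program_grade, ]
    for (j in seq_len(nrow(sers))) {
      out[[length(out) + 1]] <- period_volumes(ids, doses, sp, sers[j, ])
    }
  }
  structure(bind_rows(out), class = c("sbip_volume", "tbl_df", "tbl",
                                      "data.frame"))
}

#' Annual catch-up uptake for a grade program
#'
#' Sums catch-up doses across all pandemic cohorts of one grade program into
#' annual July 1 - June 30 windows (labelled like school years, e.g.
#' `"2021-2022"` for July 2021 through June 2022), and returns the per-window
#' counts together with their maximum and mean over complete windows.
#' Windows start at the first July following the earliest pandemic cohort's
#' grade year (before which no catch-up dose can exist) and must end on or
#' before the study end to count as complete.
#'
#' @param volumes Volume tibble from [volume_table()].
#' @param cohorts The `cohort_set`.
#' @param program_grade Grade program to summarise.
#' @param antigen_group Series to summarise.
#' @param observation_end Study end month.
#' @return A list with `by_window` (tibble: window, catchup_count),
#'   `max_annual` and `mean_annual`.
#' @export
annual_catchup_uptake <- function(volumes, cohorts, program_grade,
                                  antigen_group, observation_end = "2024-07") {
  specs <- cohorts$specs
  pans <- specs[specs$program_grade == program_grade &
                specs$role == "pandemic", ]
  if (nrow(pans) == 0) abort("No pandemic cohorts for this grade program")
  v <- volumes %>%
    filter(.data$cohort_id %in% pans$cohort_id,
           .data$antigen_group == !!antigen_group)

  # July-June window label for each period: summer "Y" and school year
  # "Y-(Y+1)" both fall in window "Y-(Y+1)"
  window_of <- function(period, period_years) {
    out <- period_years
    s <- period == "summer"
    out[s] <- sprintf("%s-%d", period_years[s], as.integer(period_years[s]) + 1L)
    out
  }
  first_july <- min(school_year_start_year(pans$school_year)) + 1L
  end_idx <- ym_index(observation_end)
  complete_windows <- character(0)
  y <- first_july
  while (ym_index(sprintf("%d-06", y + 1L)) <= end_idx) {
    complete_windows <- c(complete_windows, sprintf("%d-%d", y, y + 1L))
    y <- y + 1L
  }
  if (length(complete_windows) < 1) {
    abort("Fewer than one complete July-June catch-up window in the study range")
  }
  by_window <- v %>%
    mutate(window = window_of(.data$period, .data$period_years)) %>%
    filter(.data$window %in% complete_windows) %>%
    group_by(.data$window) %>%
    summarise(catchup_count = sum(.data$catchup_count), .groups = "drop") %>%
    full_join(tibble(window = complete_windows), by = "window") %>%
    mutate(catchup_count = dplyr::coalesce(.data$catchup_count, 0L)) %>%
    arrange(.data$window)
  list(by_window = by_window,
       max_annual = max(by_window$catchup_count),
       mean_annual = mean(by_window$catchup_count))
}
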