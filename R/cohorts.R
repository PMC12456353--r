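# Grade-year cohort construction: eligibility by enrollment, exclusion
# flags, age window as of September 1, and censoring relative to the study
# end. Exclusion reasons are tallied with a fixed precedence (flag, then
# age, then censoring, then repeat enrollment) so tallies are deterministic.

#' Cohort specifications
#'
#' `cohort_spec()` describes one grade-year cohort: its enrolled grade and
#' school year, its role (`prepandemic` counterfactual or `pandemic`), the
#' inclusive age window as of September 1, the reference month from which
#' month-aligned comparisons are counted (July of the grade-year's end), the
#' month coverage tracking starts (September of the grade year for Grade 1
#' programs, which act as a catch-up opportunity for preschool doses;
#' otherwise the reference month), and the study end month.
#'
#' @param program_grade Grade of the school program the cohort belongs to.
#' @param grade Enrolled grade (differs from `program_grade` only for the
#'   Grade 6 program's prepandemic cohort, which was enrolled in Grade 5).
#' @param school_year School-year label, e.g. `"2019-2020"`.
#' @param role `"prepandemic"` or `"pandemic"`.
#' @param age_min,age_max Inclusive completed-age window as of September 1.
#' @param observation_end Study end month (`"YYYY-MM"`).
#' @param coverage_start First month of coverage tracking (`"YYYY-MM"`);
#'   defaults to September of the grade year when `track_from_entry` is
#'   `TRUE`, otherwise to the reference month.
#' @param track_from_entry Track coverage from school entry (Grade 1 style).
#' @return A one-row tibble.
#' @export
cohort_spec <- function(program_grade, grade, school_year,
                        role = c("pandemic", "prepandemic"),
                        age_min, age_max, observation_end = "2024-07",
                        coverage_start = NULL, track_from_entry = FALSE) {
  role <- match.arg(role)
  y1 <- school_year_start_year(school_year)
  if (age_min > age_max) abort("age_min must be <= age_max",
                               class = "sbip_config_error")
  reference_month <- sprintf("%d-07", y1 + 1L)
  coverage_start <- coverage_start %||%
    (if (track_from_entry) sprintf("%d-09", y1) else reference_month)
  tibble(
    cohort_id = sprintf("G%d_%s", as.integer(program_grade), school_year),
    program_grade = as.integer(program_grade), grade = as.integer(grade),
    school_year = school_year, role = role,
    age_min = as.integer(age_min), age_max = as.integer(age_max),
    reference_month = reference_month, coverage_start = coverage_start,
    observation_end = observation_end
  )
}

#' Default study cohort specifications
#'
#' Emits the 15 default specs: for each of the Grade 1, 6 and 9 programs,
#' one prepandemic cohort and the four pandemic cohorts (2019-2020 through
#' 2022-2023). The Grade 1 and 9 prepandemic cohorts are the 2018-2019
#' grade-years; the Grade 6 program's prepandemic cohort is the Grade 5
#' group of 2017-2018 (the target grade for delivery moved from Grade 5 to
#' Grade 6 in 2018-2019, leaving no program year to compare). Age windows
#' are 5-7 for Grade 1, 9-11 for Grade 5, 10-12 for Grade 6 and 13-15 for
#' Grade 9.
#'
#' @param observation_end Study end month (default `"2024-07"`).
#' @param pandemic_years School-year labels of the pandemic cohorts.
#' @return A tibble of cohort specs (one row each).
#' @export
default_cohort_specs <- function(observation_end = "2024-07",
                                 pandemic_years = c("2019-2020", "2020-2021",
                                                    "2021-2022", "2022-2023")) {
  age_window <- function(grade) {
    switch(as.character(grade), "1" = c(5L, 7L), "5" = c(9L, 11L),
           "6" = c(10L, 12L), "9" = c(13L, 15L),
           abort(sprintf("No default age window for grade %s", grade)))
  }
  specs <- list()
  for (pg in c(1L, 6L, 9L)) {
    pre_grade <- if (pg == 6L) 5L else pg
    pre_year <- if (pg == 6L) "2017-2018" else "2018-2019"
    w <- age_window(pre_grade)
    specs[[length(specs) + 1]] <- cohort_spec(
      pg, pre_grade, pre_year, role = "prepandemic",
      age_min = w[1], age_max = w[2], observation_end = observation_end,
      track_from_entry = pg == 1L)
    w <- age_window(pg)
    for (yr in pandemic_years) {
      specs[[length(specs) + 1]] <- cohort_spec(
        pg, pg, yr, role = "pandemic",
        age_min = w[1], age_max = w[2], observation_end = observation_end,
        track_from_entry = pg == 1L)
    }
  }
  bind_rows(specs)
}

#' Build grade-year cohorts from enrollment data
#'
#' A person is a member of a cohort iff they were enrolled in the spec's
#' grade and school year, carry no exclusion flag, have a completed age as
#' of September 1 inside the spec's age window, are not censored (died or
#' out-migrated) on or before the study end, and were not already assigned
#' to an earlier cohort of the same program grade (repeaters join their
#' first qualifying cohort). Every rejected enrollment is tallied under its
#' first matching reason, in the fixed order flag > age > censoring >
#' repeat_enrollment.
#'
#' @param persons,enrollments Registry tibbles from [read_registry()] or
#'   [simulate_registry()].
#' @param specs Cohort spec tibble from [default_cohort_specs()] or rows of
#'   [cohort_spec()].
#' @return A `cohort_set` object: a list with `members` (tibble: cohort_id,
#'   program_grade, grade, school_year, role, person_id), `exclusions`
#'   (tibble: cohort_id, reason, n) and `specs`.
#' @export
build_cohorts <- function(persons, enrollments, specs) {
  specs <- as_tibble(specs)
  if (anyDuplicated(specs[, c("grade", "school_year")])) {
    abort("Overlapping cohort specs: same grade and school_year given twice",
          class = "sbip_config_error")
  }
  specs <- arrange(specs, .data$program_grade, .data$school_year)

  members_l <- list(); excl_l <- list()
  assigned <- list()  # program_grade -> person_ids already placed

  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    rows <- enrollments %>%
      filter(.data$grade == sp$grade, .data$school_year == sp$school_year) %>%
      left_join(select(persons, "person_id", "birth_date", "censor_date"),
                by = "person_id")
    if (nrow(rows) == 0) {
      members_l[[i]] <- tibble(cohort_id = character(0), person_id = character(0))
      next
    }
    sept1 <- as.Date(sprintf("%d-09-01",
                             school_year_start_year(sp$school_year)))
    age <- age_on(rows$birth_date, sept1)
    flag <- rows$exclusion_flags != "" & !is.na(rows$exclusion_flags)
    first_flag <- vapply(strsplit(rows$exclusion_flags, ";", fixed = TRUE),
                         function(f) if (length(f)) f[[1]] else "",
                         character(1))
    bad_age <- age < sp$age_min | age > sp$age_max
    censored <- !is.na(rows$censor_date) &
      rows$censor_date <= month_end(sp$observation_end)
    prev <- assigned[[as.character(sp$program_grade)]] %||% character(0)
    repeater <- rows$person_id %in% prev

    reason <- rep(NA_character_, nrow(rows))
    reason[repeater] <- "repeat_enrollment"
    reason[censored] <- "censoring"
    reason[bad_age]  <- "age"
    reason[flag]     <- first_flag[flag]   # highest precedence wins last

    keep <- is.na(reason)
    members_l[[i]] <- tibble(cohort_id = sp$cohort_id,
                             person_id = rows$person_id[keep])
    if (any(!keep)) {
      excl_l[[length(excl_l) + 1]] <- tibble(cohort_id = sp$cohort_id,
                                             reason = reason[!keep]) %>%
        count(.data$cohort_id, .data$reason, name = "n")
    }
    assigned[[as.character(sp$program_grade)]] <- c(prev, rows$person_id[keep])
  }

  members <- bind_rows(members_l) %>%
    left_join(select(specs, "cohort_id", "program_grade", "grade",
                     "school_year", "role"),
              by = "cohort_id") %>%
    select("cohort_id", "program_grade", "grade", "school_year", "role",
           "person_id")
  exclusions <- if (length(excl_l)) {
    bind_rows(excl_l) %>% arrange(.data$cohort_id, .data$reason)
  } else {
    tibble(cohort_id = character(0), reason = character(0), n = integer(0))
  }
  structure(list(members = members, exclusions = exclusions, specs = specs),
            class = "cohort_set")
}

#' @export
print.cohort_set <- function(x, ...) {
  cat("<cohort_set>", nrow(x$specs), "cohorts,",
      nrow(x$members), "members,",
      sum(x$exclusions$n), "exclusions\n")
  print(glance(x), ...)
  invisible(x)
}

#' @describeIn build_cohorts `tidy()` returns the member table.
#' @param x A `cohort_set`.
#' @param ... Unused.
#' @method tidy cohort_set
#' @export
tidy.cohort_set <- function(x, ...) x$members

#' @describeIn build_cohorts `glance()` returns one row per cohort with its
#'   size and exclusion total.
#' @method glance cohort_set
#' @export
glance.cohort_set <- function(x, ...) {
  sizes <- count(x$members, .data$cohort_id, name = "n_members")
  excl <- x$exclusions %>% group_by(.data$cohort_id) %>%
    summarise(n_excluded = sum(.data$n), .groups = "drop")
  x$specs %>%
    select("cohort_id", "program_grade", "grade", "school_year", "role") %>%
    left_join(sizes, by = "cohort_id") %>%
    left_join(excl, by = "cohort_id") %>%
    mutate(n_members = dplyr::coalesce(.data$n_members, 0L),
           n_excluded = dplyr::coalesce(.data$n_excluded, 0L))
}
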