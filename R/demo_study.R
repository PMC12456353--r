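# The bundled synthetic study: generator settings and the matching analysis
# series registry. The synthetic world abstracts each program's tracked
# series to the doses visible to the school program: Grade 1 series are
# two-dose with high prior coverage at school entry (the program is a
# catch-up opportunity for preschool doses), Grade 6 HPV / hepatitis B are
# two-dose in-year series (three-dose for the Grade 5 prepandemic cohort
# year), and Grade 9 series are single adolescent doses. The disruption
# window spans March 2020 through June 2021, with scheduled hazards
# multiplied by 0.2 inside it, and a modest multi-year catch-up hazard
# afterwards.

#' Analysis series registry matching the synthetic generator
#'
#' @return A series tibble usable wherever [default_series_registry()] is.
#' @export
demo_series_registry <- function() {
  bind_rows(
    series_spec("measles_containing", 1, doses = 2, label = "MMR/MMRV"),
    series_spec("pertussis_containing", 1, doses = 2, label = "DTaP-IPV"),
    series_spec("hpv", 6, doses = 2,
                doses_by_cohort_year = list("2017-2018" = 3), label = "HPV"),
    series_spec("hepatitis_b", 6, doses = 2,
                doses_by_cohort_year = list("2017-2018" = 3),
                label = "Hepatitis B"),
    series_spec("men_acyw", 9, doses = 1, label = "MenC-ACYW"),
    series_spec("pertussis_containing", 9, doses = 1, label = "Tdap")
  )
}

#' Generator-side series for the bundled synthetic study
#'
#' One [sim_series()] row per grade and antigen group; the Grade 5 rows
#' serve the Grade 6 program's prepandemic (2017-2018 Grade 5) cohort with
#' its 3-dose series.
#'
#' @param catchup_hazard Per-month post-schedule catch-up probability shared
#'   by all series.
#' @return A tibble of simulated series definitions.
#' @export
demo_sim_series <- function(catchup_hazard = 0.025) {
  two_clinics <- function(h1, h2, o1, o2) {
    s <- c(h1, h2); names(s) <- c(o1, o2); s
  }
  entry_catchup <- c("2" = 0.05, "3" = 0.05, "4" = 0.05, "5" = 0.05,
                     "6" = 0.05, "7" = 0.05)
  bind_rows(
    sim_series("measles_containing", 1, doses = 2,
               schedule = entry_catchup, catchup_hazard = catchup_hazard,
               prior_coverage = 0.76),
    sim_series("pertussis_containing", 1, doses = 2,
               schedule = entry_catchup, catchup_hazard = catchup_hazard,
               prior_coverage = 0.74),
    sim_series("hpv", 5, doses = 3,
               schedule = list(two_clinics(0.55, 0.35, 1, 2),
                               two_clinics(0.55, 0.35, 4, 5),
                               two_clinics(0.55, 0.35, 7, 8)),
               catchup_hazard = catchup_hazard),
    sim_series("hepatitis_b", 5, doses = 3,
               schedule = list(two_clinics(0.65, 0.40, 1, 2),
                               two_clinics(0.65, 0.40, 4, 5),
                               two_clinics(0.65, 0.40, 7, 8)),
               catchup_hazard = catchup_hazard),
    sim_series("hpv", 6, doses = 2,
               schedule = list(two_clinics(0.55, 0.35, 1, 2),
                               two_clinics(0.55, 0.35, 7, 8)),
               catchup_hazard = catchup_hazard),
    sim_series("hepatitis_b", 6, doses = 2,
               schedule = list(two_clinics(0.65, 0.40, 1, 2),
                               two_clinics(0.65, 0.40, 7, 8)),
               catchup_hazard = catchup_hazard),
    sim_series("men_acyw", 9, doses = 1,
               schedule = two_clinics(0.70, 0.50, 2, 3),
               catchup_hazard = catchup_hazard),
    sim_series("pertussis_containing", 9, doses = 1,
               schedule = two_clinics(0.70, 0.50, 2, 3),
               catchup_hazard = catchup_hazard)
  )
}

#' Default synthetic-study simulation configuration
#'
#' Fifteen cohorts matching [default_cohort_specs()] (the Grade 6 program's
#' prepandemic cohort is enrolled in Grade 5, 2017-2018, with its 3-dose
#' series), with school-year-concentrated scheduled hazards, a refuser
#' fraction of 0.08, a disruption window from March 2020 through June 2021
#' multiplying scheduled hazards by 0.2, and a post-schedule catch-up hazard
#' of 0.025 per month.
#'
#' @param seed Integer RNG seed.
#' @param cohort_size Members per grade-year cohort (default 5000).
#' @param refuser_fraction,disruption_window,disruption_multiplier,catchup_hazard
#'   Override the defaults above.
#' @param observation_end Last simulated month.
#' @return A [simulation_config()].
#' @export
demo_sim_config <- function(seed, cohort_size = 5000,
                            refuser_fraction = 0.08,
                            disruption_window = c("2020-03", "2021-06"),
                            disruption_multiplier = 0.2,
                            catchup_hazard = 0.025,
                            observation_end = "2024-07") {
  specs <- default_cohort_specs(observation_end = observation_end)
  cohorts <- tibble(grade = specs$grade, school_year = specs$school_year,
                    size = as.integer(cohort_size))
  cohorts <- distinct(cohorts, .data$grade, .data$school_year,
                      .keep_all = TRUE)
  simulation_config(
    seed = seed, cohorts = cohorts,
    series = demo_sim_series(catchup_hazard = catchup_hazard),
    refuser_fraction = refuser_fraction,
    disruption_window = disruption_window,
    disruption_multiplier = disruption_multiplier,
    observation_end = observation_end
  )
}
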