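# Study configuration: either three registry table paths or a simulate
# block (never both), plus cohort specs, the series registry, the study end
# month and the CI level. Configurations can be built in R or read from a
# YAML file; a fully commented example ships in inst/extdata/.

#' Build a study configuration
#'
#' @param seed Integer seed used for any simulation randomness.
#' @param inputs `NULL`, or a list with `persons`, `enrollments`, `doses`
#'   paths to registry CSVs. Exactly one of `inputs` / `simulate` must be
#'   given.
#' @param simulate `NULL`, or a list of synthetic-study settings understood
#'   by [demo_sim_config()]: `cohort_size`, `refuser_fraction`,
#'   `disruption_window`, `disruption_multiplier`, `catchup_hazard`.
#' @param cohorts `"default"` for [default_cohort_specs()], or a cohort spec
#'   tibble.
#' @param series `"default"` for [default_series_registry()] (real-world
#'   dose coding), `"default_synthetic"` for [demo_series_registry()]
#'   (matches the synthetic generator), or a series tibble.
#' @param observation_end Study end month (`"YYYY-MM"`).
#' @param ci_level Confidence level for all intervals.
#' @return A `study_config` list.
#' @export
study_config <- function(seed, inputs = NULL, simulate = NULL,
                         cohorts = "default", series = NULL,
                         observation_end = "2024-07", ci_level = 0.95) {
  if (is.null(inputs) == is.null(simulate)) {
    abort("Exactly one of `inputs` and `simulate` must be provided",
          class = "sbip_config_error")
  }
  if (!is.null(inputs)) {
    stopifnot(all(c("persons", "enrollments", "doses") %in% names(inputs)))
  }
  if (ci_level <= 0 || ci_level >= 1) {
    abort("ci_level must be in (0, 1)", class = "sbip_config_error")
  }
  ym_index(observation_end)
  series <- series %||% (if (is.null(simulate)) "default" else "default_synthetic")
  structure(list(seed = as.integer(seed), inputs = inputs, simulate = simulate,
                 cohorts = cohorts, series = series,
                 observation_end = observation_end, ci_level = ci_level),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path Path to a YAML file; see the commented example at
#'   `system.file("extdata", "demo_config.yaml", package = "sbipcatchup")`.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate) && !is.null(y$simulate$disruption_window)) {
    y$simulate$disruption_window <- as.character(y$simulate$disruption_window)
  }
  study_config(
    seed = y$seed %||% 1L,
    inputs = y$inputs,
    simulate = y$simulate,
    cohorts = y$cohorts %||% "default",
    series = y$series,
    observation_end = y$observation_end %||% "2024-07",
    ci_level = y$ci_level %||% 0.95
  )
}

resolve_cohort_specs <- function(config) {
  if (identical(config$cohorts, "default")) {
    default_cohort_specs(observation_end = config$observation_end)
  } else {
    as_tibble(config$cohorts)
  }
}

resolve_series_registry <- function(config) {
  if (identical(config$series, "default")) {
    default_series_registry()
  } else if (identical(config$series, "default_synthetic")) {
    demo_series_registry()
  } else if (is.data.frame(config$series)) {
    config$series
  } else if (is.list(config$series)) {
    bind_rows(lapply(config$series, function(s) {
      series_spec(s$antigen_group, s$grade, doses = s$doses %||% 1L,
                  doses_by_cohort_year = s$doses_by_cohort_year,
                  threshold_mode = s$threshold_mode %||% "complete",
                  label = s$label %||% s$antigen_group)
    }))
  } else {
    abort("Unrecognised `series` entry in study config",
          class = "sbip_config_error")
  }
}
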