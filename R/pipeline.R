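# End-to-end orchestration: simulate or read the registry, build cohorts,
# compute coverage, counterfactual differences, administration volumes and
# the deficit report, then write every result table plus a run manifest.
# All stages run in memory first; files are only written once every stage
# has succeeded, so a failed run leaves no partial outputs. Reruns with an
# identical configuration are byte-identical.

stage <- function(name, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "sbip_stage_error", parent = e)
    }),
    message = function(m) {
      inform(sprintf("[%s] %s", name, trimws(conditionMessage(m))))
      invokeRestart("muffleMessage")
    }
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read), build-cohorts, coverage, diff, volume and
#' deficits, and writes `cohorts.csv`, `exclusions.csv`, `coverage.csv`,
#' `coverage_diff.csv`, `volume.csv`, `annual_catchup.csv`, `deficits.csv`
#' (plus, for simulated studies, the three registry CSVs and
#' `ground_truth.csv`) and a `manifest.json` recording the configuration
#' hash, seed, per-table row counts and package version.
#'
#' @param config A `study_config` from [study_config()] or
#'   [read_study_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the configuration's seed.
#' @return Invisibly, a list with all in-memory results (`registry`,
#'   `cohorts`, `coverage`, `differences`, `volumes`, `annual_catchup`,
#'   `deficits`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)

  registry <- if (!is.null(config$simulate)) {
    stage("simulate", {
      s <- config$simulate
      cfg <- demo_sim_config(
        seed = config$seed,
        cohort_size = s$cohort_size %||% 5000,
        refuser_fraction = s$refuser_fraction %||% 0.08,
        disruption_window = s$disruption_window %||% c("2020-03", "2021-06"),
        disruption_multiplier = s$disruption_multiplier %||% 0.2,
        catchup_hazard = s$catchup_hazard %||% 0.025,
        observation_end = config$observation_end)
      simulate_registry(cfg)
    })
  } else {
    stage("read", read_registry(config$inputs$persons,
                                config$inputs$enrollments,
                                config$inputs$doses))
  }

  specs <- resolve_cohort_specs(config)
  series_registry <- resolve_series_registry(config)

  cohorts <- stage("build-cohorts",
                   build_cohorts(registry$persons, registry$enrollments, specs))
  coverage <- stage("coverage",
                    coverage_curves(cohorts, registry$doses, series_registry,
                                    level = config$ci_level))
  differences <- stage("diff",
                       coverage_differences(coverage, cohorts,
                                            level = config$ci_level))
  volumes <- stage("volume",
                   volume_table(cohorts, registry$doses, series_registry))
  annual <- stage("volume", {
    rows <- list()
    for (pg in sort(unique(series_registry$grade))) {
      for (ag in unique(series_registry$antigen_group[
          series_registry$grade == pg])) {
        u <- annual_catchup_uptake(volumes, cohorts, pg, ag,
                                   observation_end = config$observation_end)
        rows[[length(rows) + 1]] <- mutate(u$by_window, program_grade = pg,
                                           antigen_group = ag)
      }
    }
    bind_rows(rows) %>%
      select("program_grade", "antigen_group", "window", "catchup_count")
  })
  deficits <- stage("deficits",
                    deficit_table(coverage, volumes, cohorts, series_registry))

  manifest <- list(
    tool = "sbipcatchup",
    version = as.character(packageVersion("sbipcatchup")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    tables = list(
      cohorts = nrow(cohorts$members), exclusions = nrow(cohorts$exclusions),
      coverage = nrow(coverage), coverage_diff = nrow(differences),
      volume = nrow(volumes), annual_catchup = nrow(annual),
      deficits = nrow(deficits))
  )

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tryCatch({
    wt <- function(x, name) {
      p <- file.path(out_dir, name)
      write_table(x, p)
      written <<- c(written, p)
    }
    if (!is.null(config$simulate)) {
      wt(registry$persons, "persons.csv")
      wt(registry$enrollments, "enrollments.csv")
      wt(registry$doses, "doses.csv")
      wt(registry$ground_truth, "ground_truth.csv")
    }
    wt(cohorts$members, "cohorts.csv")
    wt(cohorts$exclusions, "exclusions.csv")
    wt(as_tibble(coverage), "coverage.csv")
    wt(as_tibble(differences), "coverage_diff.csv")
    wt(as_tibble(volumes), "volume.csv")
    wt(annual, "annual_catchup.csv")
    wt(tidy(deficits), "deficits.csv")
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, mp)
  }, error = function(e) {
    unlink(written)
    abort(sprintf("Pipeline stage 'write' failed: %s", conditionMessage(e)),
          class = "sbip_stage_error", parent = e)
  })

  inform(sprintf("Pipeline complete: %d members, %d exclusions, %d result tables in %s",
                 nrow(cohorts$members), sum(cohorts$exclusions$n), 7L, out_dir))
  invisible(list(registry = registry, cohorts = cohorts, coverage = coverage,
                 differences = differences, volumes = volumes,
                 annual_catchup = annual, deficits = deficits,
                 manifest = manifest))
}
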