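# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (enumeration, per-person loops, qbeta tail inversion) and never call
# the code paths they check.

write_tiny_registry <- function(dir,
                                persons = NULL, enrollments = NULL,
                                doses = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  persons <- persons %||% paste(
    "person_id,birth_date,censor_date,sex",
    "P1,2013-10-05,,F",
    "P2,2013-02-14,,M", sep = "\n")
  enrollments <- enrollments %||% paste(
    "person_id,school_year,grade,school_id,exclusion_flags",
    "P1,2019-2020,1,S001,",
    "P2,2019-2020,1,S001,", sep = "\n")
  doses <- doses %||% paste(
    "person_id,antigen_group,product_code,administration_date",
    "P1,measles_containing,MMR,2019-10-15",
    "P1,measles_containing,MMRV,2020-03-02",
    "P2,measles_containing,MMR,2019-11-20", sep = "\n")
  writeLines(persons, file.path(dir, "persons.csv"))
  writeLines(enrollments, file.path(dir, "enrollments.csv"))
  writeLines(doses, file.path(dir, "doses.csv"))
  list(persons = file.path(dir, "persons.csv"),
       enrollments = file.path(dir, "enrollments.csv"),
       doses = file.path(dir, "doses.csv"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-cohort, one-series simulation config used across module tests.
tiny_sim_config <- function(seed = 42, n = 500, grade = 6,
                            school_year = "2020-2021", doses = 2,
                            schedule = list(c("1" = 0.5), c("7" = 0.5)),
                            refuser_fraction = 0.1, catchup_hazard = 0.05,
                            disruption_window = NULL,
                            disruption_multiplier = 1,
                            prior_coverage = 0,
                            observation_end = "2023-07",
                            antigen_group = "hpv") {
  simulation_config(
    seed = seed,
    cohorts = data.frame(grade = grade, school_year = school_year, size = n),
    series = sim_series(antigen_group, grade, doses = doses,
                        schedule = schedule, catchup_hazard = catchup_hazard,
                        prior_coverage = prior_coverage),
    refuser_fraction = refuser_fraction,
    disruption_window = disruption_window,
    disruption_multiplier = disruption_multiplier,
    observation_end = observation_end)
}

spec_for <- function(specs, cohort_id) specs[specs$cohort_id == cohort_id, ]

# Exact Clopper-Pearson interval by beta tail inversion (independent of the
# Wilson implementation under test).
clopper_pearson <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  low <- if (k == 0) 0 else qbeta(a, k, n - k + 1)
  high <- if (k == n) 1 else qbeta(1 - a, k + 1, n - k)
  c(low, high)
}

# Exhaustive path-enumeration oracle for the k-dose monthly hazard model:
# enumerates every success/failure outcome over the months with per-month
# receipt probabilities `p`, counts paths reaching >= threshold successes.
enumerate_coverage <- function(p, threshold) {
  m <- length(p)
  total <- 0
  for (mask in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(mask)[1:m])
    prob <- prod(ifelse(bits == 1, p, 1 - p))
    if (sum(bits) >= threshold) total <- total + prob
  }
  total
}

# Per-person, per-month brute-force cumulative coverage recount.
recount_coverage <- function(member_ids, doses, antigen_group, threshold,
                             months) {
  unname(vapply(months, function(ym) {
    last_day <- month_end(ym)
    sum(vapply(member_ids, function(pid) {
      nd <- sum(doses$person_id == pid &
                doses$antigen_group == antigen_group &
                doses$administration_date <= last_day)
      nd >= threshold
    }, logical(1)))
  }, integer(1)))
}

# Anniversary-counting age oracle: completed years = number of birthday
# anniversaries on or before `ref`; a Feb 29 anniversary falls on Mar 1 in
# non-leap years.
age_oracle <- function(birth, ref) {
  anniversary <- function(j) {
    y <- as.integer(format(birth, "%Y")) + j
    m <- as.integer(format(birth, "%m")); d <- as.integer(format(birth, "%d"))
    if (m == 2 && d == 29) {
      leap <- (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
      if (!leap) { m <- 3; d <- 1 }
    }
    as.Date(sprintf("%04d-%02d-%02d", y, m, d))
  }
  j <- 0
  while (anniversary(j + 1) <= ref) j <- j + 1
  j
}

# Matched-series multi-grade study: same series definitions for prepandemic
# (2018-2019) and pandemic cohorts of every grade, so a multiplier of 1
# makes the pandemic cohorts' coverage distribution identical to the
# counterfactual's.
matched_series_study <- function(seed, n = 5000, disruption_multiplier = 1,
                                 catchup_hazard = 0.025) {
  grades <- c(1L, 6L, 9L)
  years <- c("2018-2019", "2019-2020", "2020-2021", "2021-2022", "2022-2023")
  cohorts <- expand.grid(grade = grades, school_year = years,
                         stringsAsFactors = FALSE)
  cohorts$size <- n
  sim_series_tbl <- demo_sim_series(catchup_hazard = catchup_hazard)
  sim_series_tbl <- sim_series_tbl[sim_series_tbl$grade != 5L, ]
  cfg <- simulation_config(
    seed = seed, cohorts = cohorts, series = sim_series_tbl,
    refuser_fraction = 0.08,
    disruption_window = c("2020-03", "2021-06"),
    disruption_multiplier = disruption_multiplier,
    observation_end = "2024-07")
  reg <- simulate_registry(cfg)
  aw <- list("1" = c(5L, 7L), "6" = c(10L, 12L), "9" = c(13L, 15L))
  specs <- dplyr::bind_rows(lapply(grades, function(g) {
    dplyr::bind_rows(lapply(years, function(yr) {
      cohort_spec(g, g, yr,
                  role = if (yr == "2018-2019") "prepandemic" else "pandemic",
                  age_min = aw[[as.character(g)]][1],
                  age_max = aw[[as.character(g)]][2],
                  observation_end = "2024-07",
                  track_from_entry = g == 1L)
    }))
  }))
  cs <- build_cohorts(reg$persons, reg$enrollments, specs)
  series_registry <- demo_series_registry()
  cov <- coverage_curves(cs, reg$doses, series_registry)
  # Grade 1 preschool doses predate the grade year by design; silence the
  # per-cohort exclusion notes
  vol <- suppressMessages(volume_table(cs, reg$doses, series_registry))
  list(registry = reg, cohorts = cs, coverage = cov,
       differences = coverage_differences(cov, cs),
       deficits = deficit_table(cov, vol, cs, series_registry),
       pandemic_sizes = rep(list(rep(n, 4L)),
                            nrow(series_registry)))
}

# Standard error of a deficit estimate: binomial noise in the observed
# pandemic counts plus noise in the expected count induced by estimating the
# prepandemic coverage from a cohort of size n_pre.
deficit_se <- function(p, pandemic_sizes, n_pre) {
  p <- min(max(p, 0), 1)
  sqrt(sum(pandemic_sizes) * p * (1 - p) +
         sum(pandemic_sizes)^2 * p * (1 - p) / n_pre)
}
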