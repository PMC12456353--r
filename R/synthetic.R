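# Synthetic registry generator: a discrete-time monthly vaccination hazard
# model with scheduled uptake during the grade year, a disruption window with
# suppressed hazards, a refuser fraction, post-schedule catch-up, and (for
# Grade 1 style programs) prior coverage at school entry. The closed-form
# companion `analytic_coverage()` gives the exact expected cumulative
# coverage curve of the same generative model, which parameter-recovery
# tests use as ground truth.
#
# Generative model, per person and tracked series:
#   * with probability r (refuser) no dose is ever received;
#   * with probability `prior_coverage` the person enters the grade year with
#     the full series already received (doses dated before September 1);
#   * otherwise the pending dose is received in month m with probability
#     h_m * delta(m) during its scheduled months (delta(m) = the disruption
#     multiplier inside the disruption window, 1 outside) and with the
#     catch-up hazard c in post-schedule months; at most one dose per month.
# Dose dates are drawn uniformly within the month of receipt.

#' Simulated series specification
#'
#' @param antigen_group Antigen-group label.
#' @param grade Target grade of the program delivering the series.
#' @param doses Number of doses in the series.
#' @param schedule Baseline monthly hazards during the grade year: a named
#'   numeric vector mapping month offset within the grade year (0 =
#'   September, 9 = June) to a per-month vaccination probability, or a list
#'   of such vectors, one per dose number.
#' @param catchup_hazard Per-month probability of receiving a pending dose in
#'   months after the last scheduled month.
#' @param prior_coverage Probability that a cohort member is already
#'   series-complete at September 1 of the grade year (Grade 1 programs).
#' @return A one-row tibble.
#' @export
sim_series <- function(antigen_group, grade, doses = 1L, schedule,
                       catchup_hazard = 0, prior_coverage = 0) {
  doses <- as.integer(doses)
  if (doses < 1L) abort("`doses` must be >= 1", class = "sbip_config_error")
  if (!is.list(schedule)) schedule <- rep(list(schedule), doses)
  if (length(schedule) != doses) {
    abort("`schedule` must have one hazard vector per dose",
          class = "sbip_config_error")
  }
  for (s in schedule) {
    if (length(s) == 0 || is.null(names(s)) ||
        anyNA(suppressWarnings(as.integer(names(s))))) {
      abort("Each schedule needs month offsets (0-11) as names",
            class = "sbip_config_error")
    }
    off <- as.integer(names(s))
    if (any(off < 0 | off > 11)) {
      abort("Schedule month offsets must be within the grade year (0-11)",
            class = "sbip_config_error")
    }
    check_prob(s, "schedule hazard")
  }
  check_prob(catchup_hazard, "catchup_hazard")
  check_prob(prior_coverage, "prior_coverage")
  tibble(antigen_group = antigen_group, grade = as.integer(grade),
         doses = doses, schedule = list(schedule),
         catchup_hazard = catchup_hazard, prior_coverage = prior_coverage)
}

check_prob <- function(x, what) {
  if (anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("%s must be a probability in [0, 1]", what),
          class = "sbip_config_error")
  }
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles cohorts, simulated series, and disruption parameters, validating
#' all probabilities.
#'
#' @param seed Integer RNG seed; the same configuration always yields
#'   byte-identical output tables.
#' @param cohorts Tibble (or data frame) with columns `grade`, `school_year`,
#'   `size`.
#' @param series List of [sim_series()] rows (or a tibble binding them).
#' @param refuser_fraction Probability that a person never receives any dose.
#' @param disruption_window `c(start, end)` calendar months (`"YYYY-MM"`)
#'   within which scheduled hazards are multiplied by
#'   `disruption_multiplier`, or `NULL` for no disruption.
#' @param disruption_multiplier Factor in `[0, 1]` applied to scheduled
#'   hazards inside the window (1 = no disruption).
#' @param observation_end Last simulated calendar month (`"YYYY-MM"`).
#' @param censor_fraction,exclusion_fraction Optional fractions of persons
#'   given a mid-study censor date or an enrollment exclusion flag (default
#'   0; the analytic ground truth assumes uncensored, unflagged cohorts).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed, cohorts, series,
                              refuser_fraction = 0,
                              disruption_window = NULL,
                              disruption_multiplier = 1,
                              observation_end = "2024-07",
                              censor_fraction = 0,
                              exclusion_fraction = 0) {
  cohorts <- as_tibble(cohorts)
  stopifnot(all(c("grade", "school_year", "size") %in% names(cohorts)))
  cohorts$grade <- as.integer(cohorts$grade)
  cohorts$size <- as.integer(cohorts$size)
  if (any(cohorts$size < 0)) abort("Cohort sizes must be >= 0",
                                   class = "sbip_config_error")
  school_year_start_year(cohorts$school_year)
  if (is.data.frame(series)) series <- list(series)
  series <- bind_rows(series)
  check_prob(refuser_fraction, "refuser_fraction")
  check_prob(disruption_multiplier, "disruption_multiplier")
  check_prob(censor_fraction, "censor_fraction")
  check_prob(exclusion_fraction, "exclusion_fraction")
  if (any(refuser_fraction + series$prior_coverage > 1)) {
    abort("refuser_fraction + prior_coverage must not exceed 1",
          class = "sbip_config_error")
  }
  if (!is.null(disruption_window)) {
    if (length(disruption_window) != 2 ||
        ym_index(disruption_window[1]) > ym_index(disruption_window[2])) {
      abort("disruption_window must be c(start, end) with start <= end",
            class = "sbip_config_error")
    }
  }
  ym_index(observation_end)
  structure(list(seed = as.integer(seed), cohorts = cohorts, series = series,
                 refuser_fraction = refuser_fraction,
                 disruption_window = disruption_window,
                 disruption_multiplier = disruption_multiplier,
                 observation_end = observation_end,
                 censor_fraction = censor_fraction,
                 exclusion_fraction = exclusion_fraction),
            class = "sim_config")
}

# Per-month receipt probability for dose j of a series in calendar month m,
# for a cohort starting its grade year in September of `start_ym`.
# Scheduled months use h * delta(m); months after the series' last scheduled
# month use the catch-up hazard (unscaled); earlier unscheduled months are 0.
hazard_for_month <- function(series_row, dose_j, m_idx, start_idx, config) {
  sched <- series_row$schedule[[1]][[dose_j]]
  offsets <- as.integer(names(sched))
  last_sched <- start_idx + max(vapply(series_row$schedule[[1]], function(s) {
    max(as.integer(names(s)))
  }, integer(1)))
  off <- m_idx - start_idx
  if (off %in% offsets) {
    h <- unname(sched[match(off, offsets)])
    h * disruption_delta(m_idx, config)
  } else if (m_idx > last_sched) {
    series_row$catchup_hazard
  } else {
    0
  }
}

disruption_delta <- function(m_idx, config) {
  w <- config$disruption_window
  if (is.null(w)) return(1)
  if (m_idx >= ym_index(w[1]) && m_idx <= ym_index(w[2])) {
    config$disruption_multiplier
  } else 1
}

#' Closed-form expected cumulative coverage of the generative model
#'
#' Computes the exact probability that a cohort member has received at least
#' `threshold` doses of a simulated series by the end of `month`, by dynamic
#' programming over dose-state occupancy across months (for a single-dose
#' series this reduces to
#' `prior + (1 - prior - r) * (1 - prod(1 - p_m))`).
#'
#' @param config A [simulation_config()].
#' @param grade,school_year Identify the cohort.
#' @param antigen_group Identifies the series (within the cohort's grade).
#' @param month Calendar month (`"YYYY-MM"`); vectorised.
#' @param threshold Dose threshold (default: the series' full dose count).
#' @return Numeric vector of expected coverage proportions, one per `month`.
#' @export
analytic_coverage <- function(config, grade, school_year, antigen_group,
                              month, threshold = NULL) {
  sr <- config$series[config$series$grade == grade &
                      config$series$antigen_group == antigen_group, ]
  if (nrow(sr) != 1) abort("Series not found (or ambiguous) for this grade")
  k <- sr$doses
  threshold <- as.integer(threshold %||% k)
  stopifnot(threshold >= 1, threshold <= k)
  start_idx <- ym_index(sprintf("%d-09", school_year_start_year(school_year)))
  end_idx <- ym_index(config$observation_end)
  m_idx <- ym_index(month)
  if (any(m_idx > end_idx)) abort("month beyond observation_end")

  r <- config$refuser_fraction
  prior <- sr$prior_coverage
  # occupancy over dose states 0..k for the susceptible process
  q <- c(1, rep(0, k))
  out <- numeric(length(m_idx))
  pending <- order(m_idx)
  pos <- 1
  for (m in seq.int(start_idx, end_idx)) {
    while (pos <= length(pending) && m_idx[pending[pos]] < m) {
      out[pending[pos]] <- prior + (1 - prior - r) * sum(q[(threshold + 1):(k + 1)])
      pos <- pos + 1
    }
    p <- vapply(seq_len(k), function(j) {
      hazard_for_month(sr, j, m, start_idx, config)
    }, numeric(1))
    qn <- q
    for (s in seq_len(k)) {      # state s-1 advances to s with prob p[s]
      flow <- q[s] * p[s]
      qn[s] <- qn[s] - flow
      qn[s + 1] <- qn[s + 1] + flow
    }
    q <- qn
    while (pos <= length(pending) && m_idx[pending[pos]] == m) {
      out[pending[pos]] <- prior + (1 - prior - r) * sum(q[(threshold + 1):(k + 1)])
      pos <- pos + 1
    }
  }
  while (pos <= length(pending)) {  # months before the grade year start
    out[pending[pos]] <- if (m_idx[pending[pos]] < start_idx) prior else
      prior + (1 - prior - r) * sum(q[(threshold + 1):(k + 1)])
    pos <- pos + 1
  }
  out
}

sample_product_code <- function(antigen_group, n) {
  map <- default_product_map()
  codes <- map$product_code[map$antigen_group == antigen_group]
  if (length(codes) == 0) codes <- toupper(antigen_group)
  codes[sample.int(length(codes), n, replace = TRUE)]
}

#' Simulate a linked immunization registry
#'
#' Generates person, enrollment and dose tables for every configured cohort
#' under the discrete-time hazard model, together with a `ground_truth` table
#' holding the analytic expected coverage curve for each cohort/series and
#' the analytic end-of-study deficit relative to an undisrupted
#' (multiplier = 1) reference.
#'
#' @param config A [simulation_config()].
#' @return A list with tibbles `persons`, `enrollments`, `doses`,
#'   `ground_truth`, plus the `config`.
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  end_idx <- ym_index(config$observation_end)

  persons_l <- list(); enroll_l <- list(); doses_l <- list(); gt_l <- list()
  pid_base <- 0L

  for (ci in seq_len(nrow(config$cohorts))) {
    ch <- config$cohorts[ci, ]
    n <- ch$size
    y1 <- school_year_start_year(ch$school_year)
    entry <- as.Date(sprintf("%d-09-01", y1))
    start_idx <- ym_index(sprintf("%d-09", y1))
    typical_age <- ch$grade + 5L  # age attained on Sept 1 of the grade year
    person_id <- sprintf("P%07d", pid_base + seq_len(n))
    pid_base <- pid_base + n
    if (n == 0) next

    # birth uniform over the one-year window giving exactly the typical age
    latest <- as.Date(sprintf("%d-09-01", y1 - typical_age))
    birth <- latest - sample.int(365L, n, replace = TRUE) + 1L
    censor <- as.Date(rep(NA_character_, n))
    if (config$censor_fraction > 0) {
      cens <- runif(n) < config$censor_fraction
      censor[cens] <- entry +
        sample.int(max(30L, (end_idx - start_idx) * 30L), sum(cens), replace = TRUE)
    }
    sex <- c("F", "M")[sample.int(2L, n, replace = TRUE)]
    persons_l[[ci]] <- tibble(person_id = person_id, birth_date = birth,
                              censor_date = censor, sex = sex)

    flags <- rep("", n)
    if (config$exclusion_fraction > 0) {
      fl <- runif(n) < config$exclusion_fraction
      flags[fl] <- KNOWN_EXCLUSION_FLAGS[
        sample.int(length(KNOWN_EXCLUSION_FLAGS), sum(fl), replace = TRUE)]
    }
    enroll_l[[ci]] <- tibble(
      person_id = person_id, school_year = ch$school_year, grade = ch$grade,
      school_id = sprintf("S%03d", sample.int(5L, n, replace = TRUE)),
      exclusion_flags = flags)

    u_person <- runif(n)  # shared across series: refuser status is per person
    refuser <- u_person < config$refuser_fraction

    cohort_series <- config$series[config$series$grade == ch$grade, ]
    for (si in seq_len(nrow(cohort_series))) {
      sr <- cohort_series[si, ]
      k <- sr$doses
      prior <- u_person >= config$refuser_fraction &
        u_person < config$refuser_fraction + sr$prior_coverage

      dose_person <- character(0); dose_date <- as.Date(character(0))

      if (any(prior)) {
        # full series received before school entry, spaced between ~2 months
        # of age and the September entry date
        idx <- which(prior)
        for (j in seq_len(k)) {
          frac <- j / (k + 1)
          span <- as.integer(entry - birth[idx]) - 90L
          d <- birth[idx] + 60L + floor(span * frac) +
            sample.int(31L, length(idx), replace = TRUE) - 16L
          d <- pmin(pmax(d, birth[idx] + 42L), entry - 1L)
          dose_person <- c(dose_person, person_id[idx])
          dose_date <- c(dose_date, d)
        }
      }

      active <- which(!refuser & !prior)
      state <- rep(0L, length(active))
      for (m in seq.int(start_idx, end_idx)) {
        if (length(active) == 0) break
        p_by_dose <- vapply(seq_len(k), function(j) {
          hazard_for_month(sr, j, m, start_idx, config)
        }, numeric(1))
        pending <- state < k
        if (!any(pending)) break
        p <- ifelse(pending, p_by_dose[pmin(state + 1L, k)], 0)
        hit <- runif(length(active)) < p
        if (any(hit)) {
          ndays <- as.integer(month_end(ym_from_index(m)) -
                              month_start(ym_from_index(m))) + 1L
          d <- month_start(ym_from_index(m)) +
            sample.int(ndays, sum(hit), replace = TRUE) - 1L
          dose_person <- c(dose_person, person_id[active[hit]])
          dose_date <- c(dose_date, d)
          state[hit] <- state[hit] + 1L
        }
      }

      if (length(dose_person) > 0) {
        doses_l[[length(doses_l) + 1]] <- tibble(
          person_id = dose_person, antigen_group = sr$antigen_group,
          product_code = sample_product_code(sr$antigen_group,
                                             length(dose_person)),
          administration_date = dose_date)
      }

      months <- ym_seq(ym_from_index(start_idx), config$observation_end)
      curve <- analytic_coverage(config, ch$grade, ch$school_year,
                                 sr$antigen_group, months)
      ref_config <- config
      ref_config$disruption_multiplier <- 1
      c_end <- curve[length(curve)]
      c_ref <- analytic_coverage(ref_config, ch$grade, ch$school_year,
                                 sr$antigen_group, config$observation_end)
      gt_l[[length(gt_l) + 1]] <- tibble(
        grade = ch$grade, school_year = ch$school_year,
        antigen_group = sr$antigen_group, month = months,
        expected_coverage = curve,
        expected_end_deficit = round(n * (c_end - c_ref), 6))
    }
  }

  list(persons = bind_rows(persons_l),
       enrollments = bind_rows(enroll_l),
       doses = if (length(doses_l)) bind_rows(doses_l) else
         tibble(person_id = character(0), antigen_group = character(0),
                product_code = character(0),
                administration_date = as.Date(character(0))),
       ground_truth = bind_rows(gt_l),
       config = config)
}
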