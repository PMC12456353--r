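test_that("Wilson interval hits its exact boundaries and tracks Clopper-Pearson", {
  ci <- binomial_ci(0, 50)
  expect_identical(ci$low, 0)
  ci <- binomial_ci(50, 50)
  expect_identical(ci$high, 1)
  ci <- binomial_ci(70, 100)
  expect_true(ci$low <= 0.7 && 0.7 <= ci$high)
  cp <- clopper_pearson(70, 100)
  expect_lt(abs(ci$low - cp[1]), 0.03)
  expect_lt(abs(ci$high - cp[2]), 0.03)
  expect_error(binomial_ci(1, 0), "n")
})

test_that("Wilson 95% intervals cover the truth in at least 93% of draws", {
  set.seed(2024)
  p <- 0.7; n <- 200
  k <- rbinom(2000, n, p)
  ci <- binomial_ci(k, n)
  expect_gte(mean(ci$low <= p & p <= ci$high), 0.93)
})

test_that("months_from_reference counts whole months from July of grade-year end", {
  sp <- cohort_spec(6, 6, "2019-2020", role = "pandemic",
                    age_min = 10, age_max = 12)
  expect_equal(months_from_reference(sp, "2021-07"), 12L)
  expect_equal(months_from_reference(sp, "2020-07"), 0L)
  sp1 <- cohort_spec(1, 1, "2019-2020", role = "pandemic", age_min = 5,
                     age_max = 7, track_from_entry = TRUE)
  expect_equal(months_from_reference(sp1, "2019-09"), -10L)
})

test_that("cumulative coverage counts thresholds from the completing dose", {
  sp <- cohort_spec(1, 1, "2019-2020", role = "pandemic", age_min = 5,
                    age_max = 7, track_from_entry = TRUE)
  ser <- series_spec("measles_containing", 1, doses = 2)
  doses <- tibble::tibble(
    person_id = c("A", "A"), antigen_group = "measles_containing",
    product_code = "MMR",
    administration_date = as.Date(c("2019-10-10", "2020-04-20")))
  cov <- cumulative_coverage(c("A", "B"), doses, sp, ser,
                             months = ym_seq("2019-09", "2020-06"))
  expect_equal(cov$n_covered[cov$calendar_month == "2020-03"], 0L)
  expect_equal(cov$n_covered[cov$calendar_month == "2020-04"], 1L)
  expect_equal(cov$n_total, rep(2L, 10))
  # ten members, none vaccinated -> proportion 0 with CI lower bound 0
  cov0 <- cumulative_coverage(sprintf("M%d", 1:10), doses[0, ], sp, ser,
                              months = c("2019-09", "2020-06"))
  expect_equal(cov0$proportion, c(0, 0))
  expect_equal(cov0$ci_low, c(0, 0))
  # an empty cohort is an error, never a silent division by zero
  expect_error(cumulative_coverage(character(0), doses, sp, ser), "empty")
})

test_that("coverage equals a per-person brute-force recount on a synthetic cohort", {
  cfg <- tiny_sim_config(seed = 99, n = 500, catchup_hazard = 0.04)
  reg <- simulate_registry(cfg)
  sp <- cohort_spec(6, 6, "2020-2021", role = "pandemic", age_min = 10,
                    age_max = 12, observation_end = "2023-07")
  ser <- series_spec("hpv", 6, doses = 2)
  cs <- build_cohorts(reg$persons, reg$enrollments, sp)
  months <- ym_seq("2021-07", "2023-07")
  cov <- cumulative_coverage(tidy(cs), reg$doses, sp, ser, months = months)
  expect_equal(cov$n_covered,
               recount_coverage(tidy(cs)$person_id, reg$doses, "hpv", 2L,
                                months))
  # monotonicity in calendar month
  expect_true(all(diff(cov$n_covered) >= 0))
  # threshold monotonicity: 1+ dose coverage >= complete coverage
  ser1 <- series_spec("hpv", 6, doses = 2, threshold_mode = "at_least_one")
  cov1 <- cumulative_coverage(tidy(cs), reg$doses, sp, ser1, months = months)
  expect_true(all(cov1$n_covered >= cov$n_covered))
})

test_that("per-cohort-year dose requirements drive the threshold", {
  ser <- series_spec("hpv", 6, doses = 2,
                     doses_by_cohort_year = list("2017-2018" = 3))
  expect_equal(required_doses(ser, "2017-2018"), 3L)
  expect_equal(required_doses(ser, "2019-2020"), 2L)
})

test_that("identical series difference is centred on zero with straddling CI", {
  sp <- cohort_spec(6, 6, "2020-2021", role = "pandemic", age_min = 10,
                    age_max = 12, observation_end = "2022-07")
  ser <- series_spec("hpv", 6, doses = 1)
  doses <- tibble::tibble(person_id = sprintf("A%d", 1:30),
                          antigen_group = "hpv", product_code = "HPV9",
                          administration_date = as.Date("2021-03-10"))
  cov <- cumulative_coverage(sprintf("A%d", 1:60), doses, sp, ser)
  d <- coverage_difference(cov, cov)
  expect_equal(d$diff_pp, rep(0, nrow(d)))
  expect_true(all(d$ci_low <= 0 & 0 <= d$ci_high))
  expect_error(coverage_difference(cov, dplyr::mutate(
    cov, months_from_reference = months_from_reference + 1000L)),
    "overlapping")
})

test_that("Wald difference CI half-width matches a Monte-Carlo resampling oracle", {
  # p1 = p2 = 0.5, n = 100 each: simulate 1e5 independent differences
  sp <- cohort_spec(6, 6, "2020-2021", role = "pandemic", age_min = 10,
                    age_max = 12, observation_end = "2021-08")
  ser <- series_spec("hpv", 6, doses = 1)
  mk <- function(ids_covered) tibble::tibble(
    person_id = ids_covered, antigen_group = "hpv", product_code = "HPV9",
    administration_date = as.Date("2021-07-05"))
  cov1 <- cumulative_coverage(sprintf("A%d", 1:100), mk(sprintf("A%d", 1:50)),
                              sp, ser, months = "2021-07")
  cov2 <- cumulative_coverage(sprintf("B%d", 1:100), mk(sprintf("B%d", 1:50)),
                              sp, ser, months = "2021-07")
  d <- coverage_difference(cov1, cov2)
  half_width <- (d$ci_high - d$ci_low) / 2
  set.seed(1)
  sim <- (rbinom(1e5, 100, 0.5) - rbinom(1e5, 100, 0.5)) / 100
  mc_half <- 100 * qnorm(0.975) * sd(sim)
  expect_lt(abs(half_width - mc_half), 0.5)
})

test_that("suppressed uptake shows up as the analytic coverage difference", {
  base <- list(seed = 5, n = 3000, doses = 1,
               schedule = c("1" = 0.4, "2" = 0.4),
               refuser_fraction = 0.1, catchup_hazard = 0)
  cfg_pre <- do.call(tiny_sim_config, c(base, list(school_year = "2018-2019")))
  cfg_pan <- do.call(tiny_sim_config, c(
    base, list(school_year = "2020-2021",
               disruption_window = c("2020-09", "2021-08"),
               disruption_multiplier = 0.2)))
  ser <- series_spec("hpv", 6, doses = 1)
  run_one <- function(cfg, year, role) {
    reg <- simulate_registry(cfg)
    sp <- cohort_spec(6, 6, year, role = role, age_min = 10, age_max = 12,
                      observation_end = "2023-07")
    cs <- build_cohorts(reg$persons, reg$enrollments, sp)
    list(cov = cumulative_coverage(tidy(cs), reg$doses, sp, ser), cfg = cfg,
         sp = sp)
  }
  pre <- run_one(cfg_pre, "2018-2019", "prepandemic")
  pan <- run_one(cfg_pan, "2020-2021", "pandemic")
  d <- coverage_difference(pan$cov, pre$cov)
  end_year <- d$diff_pp[d$months_from_reference == 0]
  c_pre <- analytic_coverage(cfg_pre, 6, "2018-2019", "hpv", "2019-07")
  c_pan <- analytic_coverage(cfg_pan, 6, "2020-2021", "hpv", "2021-07")
  se_pp <- 100 * sqrt(c_pre * (1 - c_pre) / 3000 + c_pan * (1 - c_pan) / 3000)
  expect_lt(abs(end_year - 100 * (c_pan - c_pre)), 3 * se_pp)
})
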