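test_that("expected counts sum real products and round half-up once", {
  expect_equal(expected_vaccinated(1.0, c(100L, 200L)), 300L)
  expect_equal(expected_vaccinated(0.0, c(100L, 200L)), 0L)
  # spreadsheet-style oracle: 0.905 * 166000 = 150230
  sizes <- c(40000L, 41000L, 42000L, 43000L)
  expect_equal(expected_vaccinated(0.905, sizes),
               as.integer(round(0.905 * sum(sizes))))
  # rounding happens once, after summation
  expect_equal(expected_vaccinated(0.5, c(1L, 1L, 1L)), 2L)  # 1.5 -> 2
})

test_that("deficit is observed minus expected; projection divides by uptake", {
  expect_equal(cumulative_deficit(100L, 100L), 0L)
  expect_equal(cumulative_deficit(150L, 100L), -50L)
  expect_equal(time_to_clear(0, 10), 0)
  expect_equal(time_to_clear(-100, 50), 2.0)
  expect_equal(time_to_clear(25, 0), 0)  # surplus needs no catch-up
  expect_error(time_to_clear(-10, 0), class = "sbip_undefined_horizon")
  expect_equal(format_years(c(0.141, 2.06)), c("0.14", "2.1"))
})

run_two_cohort_study <- function(multiplier, seed = 21, n = 5000,
                                 f_window = c("2020-09", "2021-08")) {
  cfg <- simulation_config(
    seed = seed,
    cohorts = data.frame(grade = 6,
                         school_year = c("2018-2019", "2020-2021"),
                         size = n),
    series = sim_series("hpv", 6, doses = 1, schedule = c("1" = 1),
                        catchup_hazard = 0),
    refuser_fraction = 0,
    disruption_window = f_window,
    disruption_multiplier = multiplier,
    observation_end = "2022-07")
  reg <- simulate_registry(cfg)
  specs <- dplyr::bind_rows(
    cohort_spec(6, 6, "2018-2019", role = "prepandemic", age_min = 10,
                age_max = 12, observation_end = "2022-07"),
    cohort_spec(6, 6, "2020-2021", role = "pandemic", age_min = 10,
                age_max = 12, observation_end = "2022-07"))
  cs <- build_cohorts(reg$persons, reg$enrollments, specs)
  ser <- series_spec("hpv", 6, doses = 1)
  cov <- coverage_curves(cs, reg$doses, ser)
  vol <- volume_table(cs, reg$doses, ser)
  deficit_table(cov, vol, cs, ser)
}

test_that("deficit identity holds and a known shortfall fraction is recovered", {
  # deterministic one-clinic series (h = 1): prepandemic coverage is exactly
  # 1; the pandemic cohort's clinic month falls in a disruption window with
  # multiplier 1 - f and no catch-up, leaving an unrecovered shortfall of
  # f * n
  f <- 0.08; n <- 5000
  dt <- run_two_cohort_study(multiplier = 1 - f, n = n)
  expect_equal(dt$cumulative_deficit,
               dt$observed_vaccinated - dt$expected_vaccinated)
  se <- sqrt(n * f * (1 - f))
  expect_lt(abs(dt$cumulative_deficit - (-f * n)), 3 * se)
})

test_that("an undisrupted study yields deficits within noise of zero", {
  dt <- run_two_cohort_study(multiplier = 1, seed = 33, n = 5000)
  expect_equal(dt$cumulative_deficit, 0L)  # h = 1 makes both cohorts exact
})

test_that("doubling every cohort size approximately doubles the deficit", {
  f <- 0.2
  d1 <- run_two_cohort_study(multiplier = 1 - f, seed = 8, n = 2000)
  d2 <- run_two_cohort_study(multiplier = 1 - f, seed = 8, n = 4000)
  expect_equal(d2$expected_vaccinated, 2L * d1$expected_vaccinated)
  ratio <- d2$cumulative_deficit / d1$cumulative_deficit
  expect_lt(abs(ratio - 2), 0.35)
})

test_that("full deficit table satisfies the identity and uses July-June uptake", {
  cfg <- read_study_config(system.file("extdata", "demo_config.yaml",
                                       package = "sbipcatchup"))
  cfg$simulate$cohort_size <- 250
  res <- suppressMessages(run_pipeline(cfg, withr::local_tempdir()))
  dt <- res$deficits
  expect_equal(nrow(dt), 6L)
  expect_equal(dt$cumulative_deficit,
               dt$observed_vaccinated - dt$expected_vaccinated)
  expect_true(all(dt$max_annual_uptake >= dt$avg_annual_uptake))
  expect_true(all(dt$min_years_to_clear <= dt$avg_years_to_clear,
                  na.rm = TRUE))
  gl <- glance(dt)
  expect_equal(gl$total_deficit, sum(dt$cumulative_deficit))
  expect_match(deficit_report_markdown(dt), "Cumulative deficit")
})
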