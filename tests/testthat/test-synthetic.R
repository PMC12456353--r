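test_that("degenerate configurations force the stated outcomes", {
  # all refusers -> no doses at all
  reg <- simulate_registry(tiny_sim_config(n = 50, refuser_fraction = 1))
  expect_equal(nrow(reg$doses), 0)

  # single scheduled month with h = 1, no refusers, single dose ->
  # every member has exactly one dose dated in that month
  cfg <- tiny_sim_config(n = 40, doses = 1, schedule = c("1" = 1),
                         refuser_fraction = 0, catchup_hazard = 0)
  reg <- simulate_registry(cfg)
  expect_equal(nrow(reg$doses), 40)
  expect_equal(unique(format(reg$doses$administration_date, "%Y-%m")),
               "2020-10")
})

test_that("invalid probabilities and windows are config errors", {
  expect_error(tiny_sim_config(refuser_fraction = 1.2),
               class = "sbip_config_error")
  expect_error(tiny_sim_config(schedule = list(c("1" = 1.5), c("2" = 0.1))),
               class = "sbip_config_error")
  expect_error(tiny_sim_config(disruption_window = c("2021-06", "2020-03")),
               class = "sbip_config_error")
})

test_that("same seed gives byte-identical output tables", {
  cfg <- tiny_sim_config(n = 200, seed = 7)
  r1 <- simulate_registry(cfg)
  r2 <- simulate_registry(cfg)
  expect_identical(r1$persons, r2$persons)
  expect_identical(r1$doses, r2$doses)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_registry(r1, d1); write_registry(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("empirical coverage converges to the closed form (two-month schedule)", {
  # analytic end-of-schedule coverage: (1 - r) * (1 - (1 - 0.5)^2) = 0.675
  cfg <- tiny_sim_config(seed = 11, n = 5000, doses = 1,
                         schedule = c("1" = 0.5, "2" = 0.5),
                         refuser_fraction = 0.1, catchup_hazard = 0)
  expect_equal(analytic_coverage(cfg, 6, "2020-2021", "hpv", "2020-11"),
               0.675)
  reg <- simulate_registry(cfg)
  end_nov <- as.Date("2020-11-30")
  first_dose <- tapply(reg$doses$administration_date, reg$doses$person_id, min)
  emp <- sum(first_dose <= end_nov) / 5000
  se <- sqrt(0.675 * (1 - 0.675) / 5000)
  expect_lt(abs(emp - 0.675), 3 * se)
})

test_that("analytic coverage matches direct substitution and enumeration", {
  # before any scheduled month, no prior coverage -> 0
  cfg <- tiny_sim_config(n = 10, doses = 1, schedule = c("3" = 0.4))
  expect_equal(analytic_coverage(cfg, 6, "2020-2021", "hpv", "2020-10"), 0)

  # one month h = 0.4 suppressed to delta = 0.5 -> C = (1 - r) * 0.2
  cfg <- tiny_sim_config(n = 10, doses = 1, schedule = c("3" = 0.4),
                         refuser_fraction = 0.1,
                         disruption_window = c("2020-12", "2020-12"),
                         disruption_multiplier = 0.5, catchup_hazard = 0)
  expect_equal(analytic_coverage(cfg, 6, "2020-2021", "hpv", "2020-12"),
               0.9 * 0.2)

  # 2-dose series over 3 scheduled months, h = 0.5 each: dynamic programme
  # must agree with exhaustive enumeration over all 2^3 outcome paths
  cfg <- tiny_sim_config(n = 10, doses = 2, refuser_fraction = 0,
                         schedule = rep(list(c("0" = 0.5, "1" = 0.5,
                                               "2" = 0.5)), 2),
                         catchup_hazard = 0)
  got <- analytic_coverage(cfg, 6, "2020-2021", "hpv",
                           c("2020-09", "2020-10", "2020-11"))
  want <- vapply(1:3, function(m) {
    enumerate_coverage(rep(0.5, m), threshold = 2)
  }, numeric(1))
  expect_equal(got, want)
})

test_that("prior coverage at entry shifts the whole curve by the prior mass", {
  cfg <- tiny_sim_config(n = 400, grade = 1, doses = 2,
                         schedule = rep(list(c("2" = 0.1)), 2),
                         prior_coverage = 0.7, refuser_fraction = 0.1,
                         catchup_hazard = 0.02,
                         antigen_group = "measles_containing")
  # entry month: only the prior-complete mass is covered
  expect_equal(
    analytic_coverage(cfg, 1, "2020-2021", "measles_containing", "2020-09"),
    0.7)
  reg <- simulate_registry(cfg)
  entry_doses <- reg$doses[reg$doses$administration_date < as.Date("2020-09-01"), ]
  complete_at_entry <- sum(table(entry_doses$person_id) >= 2)
  se <- sqrt(0.7 * 0.3 / 400)
  expect_lt(abs(complete_at_entry / 400 - 0.7), 3 * se)
  # prior doses respect the birth date
  joined <- merge(entry_doses, reg$persons, by = "person_id")
  expect_true(all(joined$administration_date > joined$birth_date))
})
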