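make_person <- function(id, birth, censor = NA) {
  tibble::tibble(person_id = id, birth_date = as.Date(birth),
                 censor_date = as.Date(censor), sex = "F")
}
make_enrollment <- function(id, year = "2019-2020", grade = 1L, flags = "") {
  tibble::tibble(person_id = id, school_year = year, grade = grade,
                 school_id = "S001", exclusion_flags = flags)
}
g1_spec <- cohort_spec(1, 1, "2019-2020", role = "pandemic",
                       age_min = 5, age_max = 7, track_from_entry = TRUE)

test_that("age window boundaries as of September 1 decide membership", {
  persons <- dplyr::bind_rows(
    make_person("A", "2013-09-02"),  # age 5 on 2019-09-01: included
    make_person("B", "2013-08-31"),  # age 6: included
    make_person("C", "2011-08-15"))  # age 8: excluded under "age"
  enr <- dplyr::bind_rows(lapply(c("A", "B", "C"), make_enrollment))
  cs <- build_cohorts(persons, enr, g1_spec)
  expect_setequal(cs$members$person_id, c("A", "B"))
  expect_equal(cs$exclusions$reason, "age")
  expect_equal(cs$exclusions$n, 1L)
})

test_that("exclusion tally counts every rejection under its first reason", {
  n <- 100
  ids <- sprintf("P%03d", seq_len(n))
  persons <- make_person(ids, "2013-10-01")
  # 5 censored mid-study; 10 flagged online_only (flag precedence beats
  # censoring for the overlap-free sets used here)
  persons$censor_date[1:5] <- as.Date("2021-01-15")
  flags <- rep("", n); flags[6:15] <- "online_only"
  enr <- make_enrollment(ids, flags = flags)
  cs <- build_cohorts(persons, enr, g1_spec)
  expect_equal(sum(cs$members$cohort_id == "G1_2019-2020"), 85L)
  tally <- setNames(cs$exclusions$n, cs$exclusions$reason)
  expect_equal(tally[["online_only"]], 10L)
  expect_equal(tally[["censoring"]], 5L)
  # conservation: members + exclusions = matching enrollment rows
  expect_equal(sum(cs$members$cohort_id == "G1_2019-2020") +
                 sum(cs$exclusions$n), n)
})

test_that("flag precedence beats age and censoring; repeaters join first cohort", {
  persons <- dplyr::bind_rows(
    make_person("X", "2011-08-15", censor = "2020-06-01"),  # flagged + old + censored
    make_person("R", "2013-10-01"))
  enr <- dplyr::bind_rows(
    make_enrollment("X", flags = "on_reserve;online_only"),
    make_enrollment("R", year = "2019-2020"),
    make_enrollment("R", year = "2020-2021"))
  specs <- dplyr::bind_rows(
    g1_spec,
    cohort_spec(1, 1, "2020-2021", role = "pandemic", age_min = 5,
                age_max = 7, track_from_entry = TRUE))
  cs <- build_cohorts(persons, enr, specs)
  expect_equal(cs$exclusions$reason[cs$exclusions$cohort_id == "G1_2019-2020"],
               "on_reserve")  # first listed flag wins over age and censoring
  expect_equal(cs$members$cohort_id[cs$members$person_id == "R"],
               "G1_2019-2020")
  expect_equal(cs$exclusions$reason[cs$exclusions$cohort_id == "G1_2020-2021"],
               "repeat_enrollment")
})

test_that("overlapping specs are a config error and empty cohorts allowed", {
  expect_error(build_cohorts(make_person("A", "2013-10-01"),
                             make_enrollment("A"),
                             dplyr::bind_rows(g1_spec, g1_spec)),
               class = "sbip_config_error")
})

test_that("default study specs encode the cohort design", {
  specs <- default_cohort_specs()
  expect_equal(nrow(specs), 15L)
  expect_equal(sum(specs$role == "pandemic"), 12L)
  g6pre <- specs[specs$program_grade == 6 & specs$role == "prepandemic", ]
  expect_equal(g6pre$grade, 5L)
  expect_equal(g6pre$school_year, "2017-2018")
  expect_equal(unique(specs$observation_end), "2024-07")
  # reference month is July of the grade-year end
  sp <- specs[specs$cohort_id == "G1_2019-2020", ]
  expect_equal(sp$reference_month, "2020-07")
  expect_equal(sp$coverage_start, "2019-09")  # Grade 1 tracked from entry
  sp9 <- specs[specs$cohort_id == "G9_2019-2020", ]
  expect_equal(sp9$coverage_start, "2020-07")
})

test_that("cohort_set tidy/glance expose members and per-cohort sizes", {
  reg <- simulate_registry(tiny_sim_config(n = 60))
  specs <- cohort_spec(6, 6, "2020-2021", role = "pandemic",
                       age_min = 10, age_max = 12)
  cs <- build_cohorts(reg$persons, reg$enrollments, specs)
  expect_equal(nrow(tidy(cs)), 60)
  gl <- glance(cs)
  expect_equal(gl$n_members, 60L)
  expect_equal(gl$n_excluded, 0L)
})
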