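# Data dictionary

All dates are ISO-8601 (`YYYY-MM-DD`); calendar months are `"YYYY-MM"`;
school-year labels `"YYYY-YYYY"` span September 1 of the first year through
August 31 of the second. Result tables are written by `write_table()` with
deterministic column order and rows sorted by all columns left to right.

## Input tables

### persons.csv
| column | type | meaning |
|---|---|---|
| person_id | string | opaque unique person identifier |
| birth_date | date | date of birth |
| censor_date | date, optional | death or out-migration date (blank if none) |
| sex | string | reporting only; not used by the analysis |

### enrollments.csv
| column | type | meaning |
|---|---|---|
| person_id | string | foreign key into persons.csv |
| school_year | label | e.g. `2019-2020`; at most one row per person per year |
| grade | integer | enrolled grade (1, 5, 6 or 9 in the default study) |
| school_id | string | opaque school identifier |
| exclusion_flags | string | semicolon-separated subset of `online_only`, `postsecondary_or_continuing`, `summer_or_evening`, `on_reserve`, `lloydminster`; may be empty |

### doses.csv
| column | type | meaning |
|---|---|---|
| person_id | string | foreign key into persons.csv |
| antigen_group | string | e.g. `measles_containing`, `pertussis_containing`, `hpv`, `hepatitis_b`, `men_acyw` |
| product_code | string | opaque product code (e.g. MMR vs MMRV) |
| administration_date | date | must be on or after the person's birth date |

## Result tables

### cohorts.csv
One row per cohort member: `cohort_id`, `program_grade`, `grade`,
`school_year`, `role` (`prepandemic`/`pandemic`), `person_id`.

### exclusions.csv
`cohort_id`, `reason` (a flag name, `age`, `censoring` or
`repeat_enrollment`), `n`. Cohort size plus the exclusion total equals the
matching enrollment rows.

### coverage.csv
One row per cohort, series and calendar month: `cohort_id`,
`antigen_group`, `dose_threshold`, `calendar_month`,
`months_from_reference` (signed whole months from July of the grade-year
end), `n_covered`, `n_total`, `proportion`, `ci_low`, `ci_high` (Wilson).

### coverage_diff.csv
One row per pandemic cohort, series and aligned month: `cohort_id`,
`antigen_group`, `months_from_reference`, `calendar_month`, `diff_pp`
(pandemic minus prepandemic, percentage points), `ci_low`, `ci_high`
(Wald).

### volume.csv
One row per cohort, series and period: `cohort_id`, `antigen_group`,
`period` (`school_year` or `summer`), `period_years` (`2021-2022` or
`2022`), `routine_count`, `catchup_count` (dose counts).

### annual_catchup.csv
One row per grade program, series and complete July–June window:
`program_grade`, `antigen_group`, `window` (e.g. `2021-2022` = July 2021
through June 2022), `catchup_count` summed over the grade's pandemic
cohorts.

### deficits.csv
One row per grade program and series: `program_grade`, `antigen_group`,
`series_label`, `expected_vaccinated` (prepandemic maximum coverage times
pandemic cohort sizes, rounded half-up once), `observed_vaccinated`,
`cumulative_deficit` (observed − expected; negative = shortfall),
`max_annual_uptake`, `avg_annual_uptake` (catch-up doses/year),
`min_years_to_clear`, `avg_years_to_clear`.

### ground_truth.csv (simulated studies only)
`grade`, `school_year`, `antigen_group`, `month`, `expected_coverage`
(closed-form expected cumulative coverage of the generative model),
`expected_end_deficit` (analytic end-of-study deficit relative to an
undisrupted reference).

### manifest.json
Tool name and version, seed, configuration hash, and row counts per result
table. Contains no timestamps, so identical runs are byte-identical.
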