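# Demo study configuration: a fully synthetic registry with the default
# fifteen grade-year cohorts (Grade 1, 6 and 9 programs; one prepandemic
# and four pandemic cohorts each).
#
# Exactly one of `simulate:` and `inputs:` may be present.
# To analyse real registry extracts instead, replace the simulate block with:
#   inputs:
#     persons: /path/to/persons.csv
#     enrollments: /path/to/enrollments.csv
#     doses: /path/to/doses.csv
#   series: default            # real-world dose coding (5-dose DTaP-IPV etc.)

# Seed for the synthetic registry; the same seed and config always produce
# byte-identical outputs. Overridable on the command line with --seed.
seed: 20190901

# Last month of observation for every cohort ("YYYY-MM").
observation_end: "2024-07"

# Confidence level for Wilson coverage intervals and Wald difference
# intervals.
ci_level: 0.95

simulate:
  # Members per grade-year cohort.
  cohort_size: 5000
  # Fraction of persons who never receive any dose.
  refuser_fraction: 0.08
  # Calendar window in which scheduled clinic hazards are suppressed, and
  # the multiplier applied to them inside it (1 = no disruption).
  disruption_window: ["2020-03", "2021-06"]
  disruption_multiplier: 0.2
  # Per-month probability of receiving a pending dose after the scheduled
  # grade year (drives the multi-year catch-up tail).
  catchup_hazard: 0.025

# Cohort eligibility specs: "default" = the 15 standard cohorts with their
# age windows, or an explicit list.
cohorts: default

# Series registry: "default_synthetic" matches the generator's abstracted
# dose counts (two-dose Grade 1 series, single-dose Grade 9 boosters).
series: default_synthetic
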