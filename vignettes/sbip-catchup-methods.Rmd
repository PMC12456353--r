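---
title: "Methods: coverage, counterfactual differences and catch-up deficits for school-based immunization programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage, counterfactual differences and catch-up deficits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical methods: the
measures it computes, the assumptions behind them, the choices made where
the design was genuinely open, and what the synthetic-registry tests do and
do not demonstrate about real data.

## Setting and cohort construction

School-based immunization programs (SBIPs) deliver scheduled vaccines to
target grades — in the default study design, a second measles-containing
dose and fifth pertussis-containing dose in Grade 1, the two-dose HPV and
hepatitis B series in Grade 6, and single MenC-ACYW and Tdap doses in
Grade 9. Pandemic-era school closures suppressed in-year delivery, and the
question the pipeline answers is how much of the resulting gap multi-year
catch-up has closed.

A *grade-year cohort* is the set of students enrolled in a target grade in
one school year (September 1 through August 31). Eligibility is: enrolled
in the spec's grade and year; no exclusion flag (flags arrive precomputed
in the enrollment table — the package does no school-registry or
geographic lookups); completed age as of September 1 inside the grade's
window; and no censoring (death or out-migration) on or before the study
end month. Three conventions needed fixing where registry practice is
silent:

* **Age** is attained age: a birthday falling exactly on September 1
  counts, and a February 29 birthday is attained on March 1 of non-leap
  years. The test suite checks this against an anniversary-counting oracle
  over a date grid including leap-day births.
* **Exclusion precedence** is fixed (first listed flag, then age, then
  censoring, then repeat enrollment) so that the exclusion tally is
  deterministic and sums, with the cohort size, to the matching enrollment
  rows. The precedence order does not change who is excluded, only how
  multi-reason rejections are attributed.
* **Repeaters** (enrolled in the target grade in two different years) join
  their first qualifying cohort only, keeping cohorts of the same grade
  program disjoint. Assigning them to the later cohort instead would be
  equally defensible; the choice is isolated in `build_cohorts()`.

The Grade 6 program's counterfactual is the Grade 5 cohort of 2017-2018:
delivery moved from Grade 5 to Grade 6 in 2018-2019, so no undisrupted
Grade 6 program year exists. That cohort's HPV and hepatitis B programs
were three-dose; series completion is therefore resolved per cohort year
through `required_doses()`, never hard-coded.

## Coverage, intervals, and the counterfactual difference

Cumulative coverage at month $t$ is the proportion of the closed cohort
with at least $k$ doses of the series' antigen group dated on or before
the last calendar day of $t$. The denominator never changes after cohort
construction: members censored during follow-up were already excluded at
build time, which trades a small survivorship restriction for curves whose
monotonicity is structural rather than approximate. An empty cohort is an
error, never a silent `NaN`.

Single proportions get the **Wilson score interval**. At the coverage
levels this setting produces (near 0 early in a Grade 6 curve, near its
asymptote late) the Wald interval degenerates to zero width while Wilson
stays calibrated; the acceptance suite checks ≥ 93% empirical coverage of
a 95% interval over 2000 binomial draws at $n = 200$, $p = 0.7$, and
agreement with an exact Clopper–Pearson oracle within 0.03 per bound. The
interval is clamped to exactly 0/1 at $k = 0$ / $k = n$.

Differences are compared at the same *months from reference* — whole
months since July of each cohort's grade-year end, negative for Grade 1
months tracked from school entry — and reported in percentage points with
a **Wald interval** on the difference of two independent proportions.
Wilson-style intervals for differences exist, but the symmetric Wald form
is what surveillance reports quote, and a Monte-Carlo resampling check
(10⁵ draws at $p_1 = p_2 = 0.5$, $n = 100$) confirms its half-width
within 0.5 pp in the regimes used here.

## Administration volume

Volume counts doses, not persons: each dose of a two-dose series
contributes one unit. A dose is *routine* if dated within September 1 –
June 30 of the cohort's grade year and *catch-up* if later; doses before
the grade year (Grade 1 preschool doses) are excluded from volume — they
belong to the preschool program's delivery, not the school program's —
but count toward coverage, which tracks total protection. Whether a
two-dose series' volume should count all doses or only initiations is not
determined by the measures themselves; the package counts all qualifying
doses of the tracked antigen group.

Annual catch-up uptake pools catch-up doses across all pandemic cohorts of
a grade program into July 1 – June 30 windows, starting at the first July
after the earliest pandemic grade year (no catch-up dose can exist
earlier) and requiring the window to end on or before the study end.
Uptake is computed per (grade, series): the deficit table reports
per-series clearing times, so pooling vaccines within a grade would mix
denominators.

## Deficits and time to clear

The expected number vaccinated applies the prepandemic cohort's *maximum
observed coverage* (with monotone cumulative curves, its study-end value)
to each pandemic cohort's size, sums as reals, and rounds half-up once at
the end — rounding per cohort first would accumulate up to half a count
per cohort. The deficit is observed minus expected, negative for a
shortfall. Time to clear is $|deficit|$ divided by annual catch-up uptake:
minimum time from the maximum annual uptake, average time from the mean; a
non-negative deficit needs zero years, and a shortfall with zero observed
uptake has no defined horizon and raises an error rather than reporting
infinity.

One interpretive point deserves emphasis: because every cohort is observed
at the same calendar study end, later pandemic cohorts have mechanically
fewer months of follow-up. With catch-up still in progress, part of a
young cohort's deficit is *pending* catch-up rather than *lost* coverage.
The deficit is still the operationally relevant quantity — it counts
children unprotected today — but it only converges to zero under no
disruption once coverage has plateaued. The null-recovery test is designed
accordingly (below).

## The synthetic registry and its ground truth

The generator draws, per person and tracked series, one of three states:
*refuser* (probability $r$; never vaccinated), *prior-complete*
(probability `prior_coverage`; the full series dated before school entry —
the Grade 1 situation, where the school program is a catch-up for
preschool doses), or *susceptible*. A susceptible person's pending dose is
received in month $m$ with probability $h_m \cdot \delta(m)$ during its
scheduled months ($\delta(m)$ = the disruption multiplier inside the
disruption window, 1 outside) and with the catch-up hazard $c$ in months
after the last scheduled month; at most one dose per month, dose dates
uniform within the month. Refuser status is drawn once per person and
shared across series, as vaccine refusal is a person-level trait.

`analytic_coverage()` computes the exact expected coverage of this model
by dynamic programming over dose-count occupancy, reducing to
$prior + (1 - prior - r)\,(1 - \prod_m (1 - p_m))$ for one dose. The test
suite verifies the DP against exhaustive enumeration of all per-month
outcome paths for a 2-dose/3-month series, and empirical curves against
the closed form within three standard errors at $n = 5000$.

The bundled demo study simulates the full fifteen-cohort design at 5000
members per cohort with $r = 0.08$, a disruption window of March 2020 –
June 2021 at multiplier 0.2, and $c = 0.025$ per month; Grade 1 prior
coverage at entry is 0.76 (measles) and 0.74 (pertussis), loosely matching
the entry coverage levels a mature program reports. The abstractions to
keep in mind when reading test results:

* Monthly resolution. The analysis is monthly, so finer-grained timing
  adds nothing testable.
* Refusers are a fixed fraction, not a waning tail — this gives a clean
  analytic asymptote for parameter recovery but understates late-converting
  hesitancy.
* All series share one catch-up hazard, so the generator does not emulate
  the grade contrasts in recovery speed (intensive Grade 6 catch-up versus
  deprioritized Grade 1) that real programs show; nothing in the pipeline
  depends on that contrast.
* The synthetic series carry only the doses the school program tracks
  (e.g. a two-dose abstraction of the five-dose childhood pertussis
  schedule, a single Tdap booster); the real-data series registry
  (`default_series_registry()`) instead encodes full lifetime dose counts.
* No sex effects, school-level clustering, or time-varying hesitancy.

Passing tests therefore demonstrate correctness of the estimators under a
known generative model — not that real registries satisfy that model. In
particular, real data contain out-of-province doses, linkage errors and
incomplete capture that the generator deliberately omits.

## Validation design and problem sizes

The acceptance suite runs four families of checks, sized to finish in a
few minutes: exact reproduction of published deficit-table arithmetic from
its printed inputs; oracle equivalence of `cumulative_coverage()` against
a per-person recount at $n = 500$; interval calibration at 2000 draws; two
matched-series studies at 5000 members per cohort; and byte-identical
reruns of the demo study.

The matched-series null studies give every grade the same 2018-2019
prepandemic year and identical series across roles, so a disruption
multiplier of 1 makes pandemic and counterfactual cohorts exchangeable.
Month-aligned coverage differences are then pure noise under *any*
catch-up hazard (alignment removes the follow-up asymmetry), and the test
checks that the pooled mean absolute difference stays below twice the mean
Wald standard error. The deficit null instead requires the plateau
argument above, so that study sets $c = 0$; its standard error includes
both the binomial noise of the observed counts and the propagated noise of
estimating prepandemic coverage from a finite cohort,
$\mathrm{SE}^2 = \sum_g n_g\,p(1-p) + (\sum_g n_g)^2\,p(1-p)/n_{pre}$ —
omitting the second term would understate the SE roughly 2.2-fold at these
sizes. Parameter recovery plants a known unrecovered shortfall (a
single-clinic series with hazard 1, suppressed to $1 - f$ for the pandemic
cohort, $f = 0.08$, no catch-up) and checks the estimated deficit within
three standard errors of $-f\,n$ at $n = 5000$.

## Determinism and numerical conventions

Every simulated study is fully determined by its seed; result tables are
written with fixed column order, rows sorted by all columns, and reals at
10 significant digits (an idempotent representation: write–read–write is
byte-identical); the run manifest carries no timestamps. Same-day
duplicate doses (same person, antigen group, date) are collapsed with a
warning — they cannot be distinct valid doses, and no published
deduplication rule exists to follow. Dose-interval validity checking is
deliberately off by default: recorded doses are counted as delivered.

## Known limitations

The pipeline assumes inputs arrive person-linked; it performs no record
linkage. Exclusion reasons beyond the five boolean flags require
preprocessing. The expected-count construction inherits the counterfactual
cohort's own pandemic exposure (its late catch-up happened during the
pandemic), which biases deficits toward zero — a property of the design,
not of the implementation. Clearing-time projections extrapolate observed
uptake linearly and ignore uptake decay or vaccine fatigue.
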