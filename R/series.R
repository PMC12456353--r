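# Vaccine series specifications: which antigen group each grade program
# tracks, how many doses complete the series (possibly differing by cohort
# year, e.g. the 3-dose vs 2-dose HPV/hepatitis B programs), and how product
# codes map to antigen groups (MMR and MMRV both count as measles-containing).

#' Define a vaccine series tracked by a grade program
#'
#' @param antigen_group Antigen-group label, e.g. `"measles_containing"`,
#'   `"pertussis_containing"`, `"hpv"`, `"hepatitis_b"`, `"men_acyw"`.
#' @param grade Target grade of the school program delivering the series.
#' @param doses Default number of doses required for series completion.
#' @param doses_by_cohort_year Named list/vector of school-year labels mapping
#'   to dose requirements overriding `doses` for specific cohort years (e.g.
#'   the 3-dose HPV program that preceded the 2-dose schedule).
#' @param threshold_mode `"complete"` (require the full dose count) or
#'   `"at_least_one"` (1+ dose coverage).
#' @param label Human-readable series label (defaults to the antigen group).
#' @return A one-row tibble describing the series.
#' @export
series_spec <- function(antigen_group, grade, doses = 1L,
                        doses_by_cohort_year = NULL,
                        threshold_mode = c("complete", "at_least_one"),
                        label = antigen_group) {
  threshold_mode <- match.arg(threshold_mode)
  doses <- as.integer(doses)
  if (doses < 1L) abort("`doses` must be >= 1")
  overrides <- as.list(doses_by_cohort_year %||% list())
  if (length(overrides) > 0) {
    school_year_start_year(names(overrides))
    if (any(unlist(overrides) < 1)) abort("Every dose requirement must be >= 1")
  }
  tibble(
    antigen_group = antigen_group,
    grade = as.integer(grade),
    doses = doses,
    doses_by_cohort_year = list(overrides),
    threshold_mode = threshold_mode,
    series_label = label
  )
}

#' Required dose count for a series in a given cohort year
#'
#' Resolves the completion threshold for one series and one cohort's school
#' year, honouring per-cohort-year overrides and the `at_least_one` mode.
#'
#' @param series A one-row series tibble from [series_spec()].
#' @param school_year School-year label of the cohort.
#' @return Integer dose threshold.
#' @export
required_doses <- function(series, school_year) {
  stopifnot(nrow(series) == 1)
  if (series$threshold_mode == "at_least_one") return(1L)
  ov <- series$doses_by_cohort_year[[1]]
  if (!is.null(ov[[school_year]])) return(as.integer(ov[[school_year]]))
  series$doses
}

#' Default series registry for the Alberta-style school program
#'
#' Grade 1 tracks the second measles-containing dose (MMR/MMRV) and the fifth
#' pertussis-containing dose (DTaP-IPV); Grade 6 the 2-dose HPV and
#' hepatitis B series (3 doses for the 2017-2018 cohort year, when a 3-dose
#' program was in place); Grade 9 the single MenC-ACYW dose and the
#' adolescent pertussis-containing booster (Tdap, the sixth lifetime
#' pertussis dose).
#'
#' @return A series registry tibble (one row per grade/series).
#' @export
default_series_registry <- function() {
  bind_rows(
    series_spec("measles_containing", 1, doses = 2, label = "MMR/MMRV"),
    series_spec("pertussis_containing", 1, doses = 5, label = "DTaP-IPV"),
    series_spec("hpv", 6, doses = 2,
                doses_by_cohort_year = list("2017-2018" = 3), label = "HPV"),
    series_spec("hepatitis_b", 6, doses = 2,
                doses_by_cohort_year = list("2017-2018" = 3),
                label = "Hepatitis B"),
    series_spec("men_acyw", 9, doses = 1, label = "MenC-ACYW"),
    series_spec("pertussis_containing", 9, doses = 6, label = "Tdap")
  )
}

#' Default product-code to antigen-group map
#'
#' Both MMR and MMRV product codes map to the `measles_containing` antigen
#' group; childhood (DTaP-IPV) and adolescent (Tdap) pertussis formulations
#' both map to `pertussis_containing`.
#'
#' @return A tibble with columns `product_code` and `antigen_group`.
#' @export
default_product_map <- function() {
  tibble(
    product_code = c("MMR", "MMRV", "DTAP-IPV", "DTAP-IPV-HIB", "TDAP",
                     "HPV9", "HPV4", "HB", "MENC-ACYW"),
    antigen_group = c("measles_containing", "measles_containing",
                      "pertussis_containing", "pertussis_containing",
                      "pertussis_containing", "hpv", "hpv", "hepatitis_b",
                      "men_acyw")
  )
}
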