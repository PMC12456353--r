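# Calendar-month arithmetic on "YYYY-MM" keys and school-year labels.
# A school-year label "2019-2020" spans Sept 1 2019 through Aug 31 2020.

#' Month-key utilities
#'
#' Calendar months are represented throughout the package as `"YYYY-MM"`
#' strings (sortable, unambiguous). `ym_index()` maps a month key to an
#' integer month count (so differences are whole months), `ym_from_index()`
#' inverts it, and `ym_seq()` enumerates an inclusive month range.
#'
#' @param ym Character vector of `"YYYY-MM"` month keys.
#' @param i Integer vector of month indices as produced by `ym_index()`.
#' @param from,to Single `"YYYY-MM"` month keys, `from <= to`.
#' @return `ym_index()` an integer vector; `ym_from_index()` and `ym_seq()`
#'   character vectors of month keys.
#' @examples
#' ym_index("2020-07") - ym_index("2019-07")  # 12
#' ym_seq("2019-11", "2020-02")
#' @export
ym_index <- function(ym) {
  stopifnot(is.character(ym))
  bad <- !is.na(ym) & !grepl("^\\d{4}-(0[1-9]|1[0-2])$", ym)
  if (any(bad)) {
    abort(sprintf("Invalid month key(s): %s (expected \"YYYY-MM\")",
                  paste(unique(ym[bad]), collapse = ", ")))
  }
  as.integer(substr(ym, 1, 4)) * 12L + as.integer(substr(ym, 6, 7)) - 1L
}

#' @rdname ym_index
#' @export
ym_from_index <- function(i) {
  i <- as.integer(i)
  sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L)
}

#' @rdname ym_index
#' @export
ym_seq <- function(from, to) {
  a <- ym_index(from); b <- ym_index(to)
  if (a > b) abort("`from` must not be after `to`")
  ym_from_index(seq.int(a, b))
}

#' @rdname ym_index
#' @export
month_start <- function(ym) {
  as.Date(paste0(ym, "-01"))
}

#' @rdname ym_index
#' @export
month_end <- function(ym) {
  month_start(ym_from_index(ym_index(ym) + 1L)) - 1L
}

#' @rdname ym_index
#' @param date A `Date` vector.
#' @export
date_to_ym <- function(date) {
  format(date, "%Y-%m")
}

#' School-year labels
#'
#' A school-year label of the form `"2019-2020"` denotes September 1 of the
#' first year through August 31 of the second. `school_year_start_year()`
#' extracts the first calendar year after validating the label;
#' `school_year_bounds()` returns the start and end `Date`s.
#'
#' @param label Character vector of school-year labels (`"YYYY-YYYY"`, second
#'   year = first year + 1).
#' @return An integer vector of start years, or a list with `start` and `end`
#'   `Date` vectors.
#' @export
school_year_start_year <- function(label) {
  ok <- grepl("^\\d{4}-\\d{4}$", label)
  if (!all(ok)) {
    abort(sprintf("Invalid school-year label(s): %s",
                  paste(unique(label[!ok]), collapse = ", ")))
  }
  y1 <- as.integer(substr(label, 1, 4))
  y2 <- as.integer(substr(label, 6, 9))
  if (any(y2 != y1 + 1L)) {
    abort(sprintf(
      "School-year label(s) must span consecutive years: %s",
      paste(unique(label[y2 != y1 + 1L]), collapse = ", ")))
  }
  y1
}

#' @rdname school_year_start_year
#' @export
school_year_bounds <- function(label) {
  y1 <- school_year_start_year(label)
  list(start = as.Date(sprintf("%d-09-01", y1)),
       end   = as.Date(sprintf("%d-08-31", y1 + 1L)))
}

#' Completed age in years at a reference date
#'
#' Attained-age convention: the birthday itself counts as having attained the
#' age (a child born 2013-09-01 is 6 on 2019-09-01). A February 29 birthday
#' is attained on March 1 in non-leap years.
#'
#' @param birth,ref `Date` vectors (recycled to common length).
#' @return Integer vector of completed years.
#' @export
age_on <- function(birth, ref) {
  stopifnot(inherits(birth, "Date"), inherits(ref, "Date"))
  by <- as.integer(format(birth, "%Y")); bm <- as.integer(format(birth, "%m"))
  bd <- as.integer(format(birth, "%d"))
  ry <- as.integer(format(ref, "%Y"));   rm <- as.integer(format(ref, "%m"))
  rd <- as.integer(format(ref, "%d"))
  age <- ry - by
  before_birthday <- (rm < bm) | (rm == bm & rd < bd)
  as.integer(age - before_birthday)
}
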