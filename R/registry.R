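# Readers/writers for the three linked registry tables and all result tables.
#
# persons.csv:     person_id,birth_date,censor_date,sex
# enrollments.csv: person_id,school_year,grade,school_id,exclusion_flags
#                  (exclusion_flags: semicolon-separated list, may be empty)
# doses.csv:       person_id,antigen_group,product_code,administration_date
# Dates are ISO-8601 (YYYY-MM-DD).

PERSON_COLS     <- c("person_id", "birth_date", "censor_date", "sex")
ENROLLMENT_COLS <- c("person_id", "school_year", "grade", "school_id",
                     "exclusion_flags")
DOSE_COLS       <- c("person_id", "antigen_group", "product_code",
                     "administration_date")

KNOWN_EXCLUSION_FLAGS <- c("online_only", "postsecondary_or_continuing",
                           "summer_or_evening", "on_reserve", "lloydminster")

read_csv_quiet <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = character())
}

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s (%s): missing required column(s): %s",
                  what, path, paste(missing, collapse = ", ")),
          class = "sbip_schema_error")
  }
}

parse_date_col <- function(x, col, what) {
  blank <- is.na(x) | x == ""
  d <- as.Date(rep(NA_character_, length(x)))
  d[!blank] <- as.Date(x[!blank], format = "%Y-%m-%d")
  # as.Date() silently accepts some malformed strings; insist on canonical form
  bad <- !blank & (is.na(d) | format(d, "%Y-%m-%d") != x)
  if (any(bad)) {
    rows <- which(bad)
    abort(sprintf(
      "%s: unparseable %s at row(s) %s (expected ISO-8601 YYYY-MM-DD): %s",
      what, col, paste(head(rows, 10), collapse = ", "),
      paste(head(unique(x[bad]), 5), collapse = ", ")),
      class = "sbip_row_error")
  }
  d
}

#' Read the three linked registry tables
#'
#' Reads and validates the person, enrollment and dose CSV tables, enforcing
#' the documented schemas (ISO-8601 dates, header row), parsing dates, and
#' checking cross-table referential integrity: every `person_id` appearing in
#' the enrollment or dose table must resolve to a row of the person table.
#'
#' Duplicate dose rows (same person, antigen group and administration date)
#' cannot be distinct valid doses and are collapsed to one with a warning.
#'
#' @param person_path,enrollment_path,dose_path Paths to the three CSV files.
#' @param dedupe_doses Collapse same-day duplicate doses (default `TRUE`).
#' @return A list with tibbles `persons`, `enrollments` and `doses`, with
#'   dates parsed to `Date` and `grade` to integer.
#' @export
read_registry <- function(person_path, enrollment_path, dose_path,
                          dedupe_doses = TRUE) {
  persons <- read_csv_quiet(person_path)
  check_columns(persons, PERSON_COLS, "person table", person_path)
  persons <- persons %>%
    select(all_of(PERSON_COLS)) %>%
    mutate(
      birth_date  = parse_date_col(.data$birth_date, "birth_date", "person table"),
      censor_date = parse_date_col(.data$censor_date, "censor_date", "person table")
    )
  if (anyDuplicated(persons$person_id)) {
    dup <- unique(persons$person_id[duplicated(persons$person_id)])
    abort(sprintf("person table: duplicate person_id(s): %s",
                  paste(head(dup, 10), collapse = ", ")),
          class = "sbip_integrity_error")
  }
  bad_censor <- !is.na(persons$censor_date) &
    persons$censor_date < persons$birth_date
  if (any(bad_censor)) {
    abort(sprintf("person table: censor_date before birth_date at row(s) %s",
                  paste(head(which(bad_censor), 10), collapse = ", ")),
          class = "sbip_integrity_error")
  }

  enrollments <- read_csv_quiet(enrollment_path)
  check_columns(enrollments, ENROLLMENT_COLS, "enrollment table", enrollment_path)
  enrollments <- enrollments %>%
    select(all_of(ENROLLMENT_COLS)) %>%
    mutate(grade = {
      g <- suppressWarnings(as.integer(.data$grade))
      if (anyNA(g)) abort("enrollment table: non-integer grade value(s)",
                          class = "sbip_row_error")
      g
    })
  school_year_start_year(unique(enrollments$school_year))
  dup_enr <- enrollments %>%
    count(.data$person_id, .data$school_year) %>%
    filter(n > 1)
  if (nrow(dup_enr) > 0) {
    abort(sprintf(
      "enrollment table: more than one enrollment per person per school year: %s",
      paste(head(dup_enr$person_id, 10), collapse = ", ")),
      class = "sbip_integrity_error")
  }

  doses <- read_csv_quiet(dose_path)
  check_columns(doses, DOSE_COLS, "dose table", dose_path)
  doses <- doses %>%
    select(all_of(DOSE_COLS)) %>%
    mutate(administration_date = parse_date_col(
      .data$administration_date, "administration_date", "dose table"))

  check_integrity <- function(df, what) {
    dangling <- setdiff(unique(df$person_id), persons$person_id)
    if (length(dangling) > 0) {
      rows <- which(df$person_id %in% dangling)
      abort(sprintf(
        "%s: person_id(s) not present in person table: %s (row(s) %s)",
        what, paste(head(dangling, 10), collapse = ", "),
        paste(head(rows, 10), collapse = ", ")),
        class = "sbip_integrity_error")
    }
  }
  check_integrity(enrollments, "enrollment table")
  check_integrity(doses, "dose table")

  early <- doses %>%
    inner_join(select(persons, "person_id", "birth_date"), by = "person_id") %>%
    filter(.data$administration_date < .data$birth_date)
  if (nrow(early) > 0) {
    abort(sprintf(
      "dose table: administration_date before birth_date for person_id(s): %s",
      paste(head(unique(early$person_id), 10), collapse = ", ")),
      class = "sbip_integrity_error")
  }

  if (dedupe_doses) {
    n0 <- nrow(doses)
    doses <- distinct(doses, .data$person_id, .data$antigen_group,
                      .data$administration_date, .keep_all = TRUE)
    if (nrow(doses) < n0) {
      warn(sprintf(
        "Collapsed %d duplicate dose row(s) (same person, antigen group and date)",
        n0 - nrow(doses)))
    }
  }

  list(persons = persons, enrollments = enrollments, doses = doses)
}

#' Write a result table as a deterministic CSV
#'
#' Writes any homogeneous record table with a fixed column order and rows
#' sorted by all columns left to right (a deterministic superset of each
#' table's natural key), so identical inputs always produce byte-identical
#' files. Reals are written with 10 significant digits; the representation is
#' idempotent under write-read-write.
#'
#' @param rows A data frame of homogeneous records (may have zero rows).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  rows <- as_tibble(rows)
  if (nrow(rows) > 0) {
    ord <- do.call(order, c(unname(as.list(rows)), list(method = "radix")))
    rows <- rows[ord, , drop = FALSE]
  }
  out <- rows
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (inherits(x, "Date")) {
      out[[j]] <- format(x, "%Y-%m-%d")
    } else if (is.double(x)) {
      s <- sprintf("%.10g", x)
      s[is.na(x)] <- NA_character_
      out[[j]] <- s
    }
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort(sprintf("Cannot write to %s", path)))
  on.exit(close(con))
  readr::write_csv(out, con, na = "")
  invisible(path)
}

#' @rdname write_table
#' @param guess_types Convert columns back to numeric/Date where all values
#'   conform (default `TRUE`).
#' @export
read_table <- function(path, guess_types = TRUE) {
  df <- read_csv_quiet(path)
  if (!guess_types) return(df)
  for (j in seq_along(df)) {
    x <- df[[j]]
    x[x == ""] <- NA_character_
    nonna <- x[!is.na(x)]
    if (length(nonna) == 0) { df[[j]] <- x; next }
    if (all(grepl("^\\d{4}-\\d{2}-\\d{2}$", nonna))) {
      df[[j]] <- as.Date(x)
    } else if (all(grepl("^-?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?$", nonna))) {
      num <- as.numeric(x)
      if (all(is.na(num) | (num == floor(num) & abs(num) < 2^31 &
                            !grepl("[.eE]", x)))) {
        df[[j]] <- as.integer(num)
      } else {
        df[[j]] <- num
      }
    } else {
      df[[j]] <- x
    }
  }
  df
}

#' Write a simulated or real registry to a directory
#'
#' @param registry A list with `persons`, `enrollments`, `doses` (and
#'   optionally `ground_truth`) tibbles, as returned by [read_registry()] or
#'   [simulate_registry()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(registry$persons, file.path(dir, "persons.csv"))
  write_table(registry$enrollments, file.path(dir, "enrollments.csv"))
  write_table(registry$doses, file.path(dir, "doses.csv"))
  if (!is.null(registry$ground_truth)) {
    write_table(registry$ground_truth, file.path(dir, "ground_truth.csv"))
  }
  invisible(dir)
}
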