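# File round-tripping ---------------------------------------------------------
#
# Cohort CSV dialect (one row per subject, UTF-8, header, dot decimals):
#   subject_id, sex, ca_years (or dob + exam_date), nolla_31..nolla_37,
#   dem_31..dem_37, optionally age_group / dataset / score / DA columns.
# Calibration models travel as JSON (see write_calibration), conversion
# tables and accuracy reports as CSV (reports also as JSON).

#' Read / write a cohort CSV
#'
#' `read_cohort()` parses the package's cohort CSV dialect. If `ca_years` is
#' absent but `dob` and `exam_date` are present, chronological age is
#' computed as the day count divided by 365.25. `write_cohort()` writes a
#' cohort tibble back to CSV.
#'
#' @param path file path.
#' @return `read_cohort()`: a cohort tibble; `write_cohort()`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"ca_years" %in% names(data)) {
    if (all(c("dob", "exam_date") %in% names(data))) {
      data$ca_years <- chronological_age(data$dob, data$exam_date)
    } else {
      abort_dentalage(
        "cohort file needs either 'ca_years' or 'dob' + 'exam_date'",
        class = "dentalage_error_incomplete_record"
      )
    }
  }
  if (!all(is.finite(data$ca_years)) || any(data$ca_years <= 0)) {
    abort_dentalage("ca_years must be finite and positive", class = "dentalage_error_input")
  }
  if ("sex" %in% names(data)) data$sex <- normalize_sex(data$sex)
  tibble::as_tibble(data)
}

#' @rdname read_cohort
#' @param data a cohort tibble.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' Write / read a conversion table CSV
#'
#' Conversion tables round-trip as two-column CSVs (`age_years`, `score`).
#'
#' @param table a conversion-table tibble from [build_conversion_table()].
#' @param path file path.
#' @return the path (write) or the tibble (read).
#' @export
write_conversion_table <- function(table, path) {
  stopifnot(all(c("age_years", "score") %in% names(table)))
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_conversion_table
#' @export
read_conversion_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("age_years", "score") %in% names(tbl))) {
    abort_dentalage("not a conversion table", class = "dentalage_error_input")
  }
  tbl
}

#' Write an accuracy report
#'
#' Writes the tibble returned by [evaluate_method()] to CSV, and optionally a
#' JSON mirror of the same rows.
#'
#' @param report an accuracy-report tibble.
#' @param path CSV output path.
#' @param json_path optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_accuracy_report <- function(report, path, json_path = NULL) {
  readr::write_csv(report, path)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
  }
  invisible(path)
}
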