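# Packaged lookup tables -----------------------------------------------------
#
# Two kinds of numeric content ship under inst/extdata/:
#  * demirjian_scores_{male,female}.csv: the classical seven-tooth
#    self-weighted stage scores (FDI 31-37); each sex's stage-H row sums to
#    100, which is asserted at load.
#  * {demirjian,nolla}_age_norms_{male,female}_synthetic.csv: SYNTHETIC
#    score-to-age conversion norms built by data-raw/build_lookup_tables.R to
#    emulate the population-mismatch biases of the classical methods on
#    cohorts from simulate_cohort(); they are not the historical norm tables.
# A md5 manifest (checksums.csv) guards against silent edits.

.lookup_cache <- new.env(parent = emptyenv())

extdata_file <- function(name) {
  path <- system.file("extdata", name, package = "dentalage")
  if (!nzchar(path)) {
    abort_dentalage(
      sprintf("packaged lookup file '%s' not found", name),
      class = "dentalage_error_configuration"
    )
  }
  path
}

verify_checksum <- function(name) {
  manifest <- readr::read_csv(extdata_file("checksums.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  expected <- manifest$md5[manifest$file == name]
  if (length(expected) == 1) {
    actual <- unname(tools::md5sum(extdata_file(name)))
    if (!identical(actual, expected)) {
      abort_dentalage(
        sprintf("checksum mismatch for packaged table '%s'", name),
        class = "dentalage_error_configuration"
      )
    }
  }
  invisible(TRUE)
}

read_lookup <- function(name) {
  if (!is.null(.lookup_cache[[name]])) {
    return(.lookup_cache[[name]])
  }
  verify_checksum(name)
  tbl <- readr::read_csv(extdata_file(name), show_col_types = FALSE, progress = FALSE)
  .lookup_cache[[name]] <- tbl
  tbl
}

#' Demirjian self-weighted stage scores
#'
#' Returns the packaged seven-tooth stage-score table for one sex: one row per
#' (tooth, stage) with the score each developmental stage contributes to the
#' 0-100 maturity score. Stage `"0"` (no calcification) and stages preceding a
#' tooth's first tabulated stage score 0; each sex's stage-H scores sum to 100.
#'
#' @param sex `"male"` or `"female"`.
#' @return A tibble with columns `tooth` (FDI 31-37), `stage` (`"0"`,
#'   `"A"`..`"H"`) and `score`.
#' @export
#' @examples
#' tab <- demirjian_score_table("male")
#' sum(tab$score[tab$stage == "H"]) # 100
demirjian_score_table <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  tbl <- read_lookup(sprintf("demirjian_scores_%s.csv", sex))
  stage_h <- sum(tbl$score[tbl$stage == "H"])
  if (abs(stage_h - 100) > 1e-6) {
    abort_dentalage(
      "corrupt Demirjian score table: stage-H scores must sum to 100",
      class = "dentalage_error_configuration"
    )
  }
  tbl
}

#' Score-to-age conversion norms
#'
#' Returns the packaged `(age, score)` norm table used to convert a maturity
#' or sum score into a dental age by piecewise-linear interpolation. The
#' shipped norms are synthetic: they are generated alongside the cohort
#' simulator to emulate the systematic over-/under-estimation the classical
#' methods show when applied to a population they were not calibrated on (see
#' `data-raw/build_lookup_tables.R`). Replace the files to use real norms.
#'
#' @param method `"demirjian"` (0-100 maturity score) or `"nolla"` (0-70 sum
#'   score).
#' @inheritParams demirjian_score_table
#' @return A tibble with columns `age` (years, strictly increasing) and
#'   `score` (strictly increasing).
#' @export
age_norm_table <- function(method = c("demirjian", "nolla"),
                           sex = c("male", "female")) {
  method <- match.arg(method)
  sex <- match.arg(sex)
  tbl <- read_lookup(sprintf("%s_age_norms_%s_synthetic.csv", method, sex))
  if (nrow(tbl) == 0) {
    abort_dentalage("empty age-norm table", class = "dentalage_error_configuration")
  }
  if (any(diff(tbl$age) <= 0) || any(diff(tbl$score) < 0)) {
    abort_dentalage(
      "corrupt age-norm table: ages must be strictly increasing and scores non-decreasing",
      class = "dentalage_error_configuration"
    )
  }
  tbl
}
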