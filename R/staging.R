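# Tooth-stage vocabularies and maturity/sum scoring --------------------------

#' Tooth and stage vocabularies
#'
#' The package works on the seven left mandibular permanent teeth, FDI codes
#' 31-37 (central incisor through second molar). Demirjian staging uses the
#' eight letters A-H plus `"0"` for no calcification; Nolla staging grades
#' each tooth on a 0-10 scale with the fractional readings .2 ("slightly more
#' than"), .5 ("about half way") and .7 ("slightly less than the next stage"),
#' i.e. the lattice k, k+0.2, k+0.5, k+0.7 for k = 0..9, plus 10.
#'
#' @return `fdi_teeth()`: integer vector of FDI codes; `demirjian_stages()`:
#'   character vector of the stage vocabulary; `nolla_lattice()`: numeric
#'   vector of admissible Nolla readings.
#' @export
fdi_teeth <- function() 31:37

#' @rdname fdi_teeth
#' @export
demirjian_stages <- function() c("0", LETTERS[1:8])

#' @rdname fdi_teeth
#' @export
nolla_lattice <- function() {
  sort(c(as.vector(outer(c(0, 0.2, 0.5, 0.7), 0:9, "+")), 10))
}

nolla_cols <- function() paste0("nolla_", fdi_teeth())
dem_cols <- function() paste0("dem_", fdi_teeth())

is_nolla_stage <- function(x) {
  lattice <- nolla_lattice()
  !is.na(x) & vapply(x, function(v) any(abs(lattice - v) < 1e-9), logical(1))
}

#' Snap values to the Nolla stage lattice
#'
#' Maps arbitrary values in \[0, 10\] to the nearest admissible Nolla reading
#' (ties resolve to the lower stage).
#'
#' @param x numeric vector.
#' @return numeric vector on the Nolla lattice.
#' @export
snap_nolla <- function(x) {
  lattice <- nolla_lattice()
  x <- pmin(pmax(x, 0), 10)
  lattice[vapply(x, function(v) which.min(abs(lattice - v)), integer(1))]
}

normalize_sex <- function(sex) {
  out <- tolower(as.character(sex))
  out[out %in% c("m", "male")] <- "male"
  out[out %in% c("f", "female")] <- "female"
  bad <- !out %in% c("male", "female")
  if (any(bad)) {
    abort_dentalage(
      sprintf("sex must be 'male' or 'female' (got '%s')", out[which(bad)[1]]),
      class = "dentalage_error_input"
    )
  }
  out
}

normalize_dem_stage <- function(stage) {
  s <- toupper(as.character(stage))
  s[s %in% c("NONE", "0")] <- "0"
  bad <- !is.na(s) & !s %in% demirjian_stages()
  if (any(bad)) {
    abort_dentalage(
      sprintf("unknown Demirjian stage '%s'", s[which(bad)[1]]),
      class = "dentalage_error_lookup"
    )
  }
  s
}

#' Chronological age in decimal years
#'
#' Computes chronological age as the day count between birth and examination
#' divided by 365.25. Vectorized; values are only rounded at presentation.
#'
#' @param dob,exam birth and examination dates (`Date` or anything
#'   `as.Date()` accepts).
#' @return numeric vector of ages in decimal years.
#' @export
#' @examples
#' chronological_age("2008-01-01", "2018-01-01")
chronological_age <- function(dob, exam) {
  dob <- as.Date(dob)
  exam <- as.Date(exam)
  days <- as.numeric(exam - dob)
  if (any(is.na(days))) {
    abort_dentalage("dates could not be parsed", class = "dentalage_error_input")
  }
  if (any(days <= 0)) {
    abort_dentalage(
      "examination date must be strictly after date of birth",
      class = "dentalage_error_invalid_interval"
    )
  }
  days / 365.25
}

check_stage_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_dentalage(
      sprintf("missing %s stage column(s): %s", what, paste(missing, collapse = ", ")),
      class = "dentalage_error_incomplete_record"
    )
  }
  invisible(TRUE)
}

#' Nolla sum score
#'
#' Adds a `nolla_sum` column: the arithmetic sum of the seven per-tooth Nolla
#' stages (`nolla_31` .. `nolla_37`), ranging from 0 (no calcification) to 70
#' (all teeth complete).
#'
#' @param data a data frame with one row per subject and columns
#'   `nolla_31`..`nolla_37` on the Nolla lattice.
#' @return `data` as a tibble with a `nolla_sum` column appended.
#' @export
#' @examples
#' tibble::tibble(
#'   nolla_31 = 10, nolla_32 = 10, nolla_33 = 9.5, nolla_34 = 8.2,
#'   nolla_35 = 7.7, nolla_36 = 9, nolla_37 = 6.5
#' ) |> add_nolla_sum()
add_nolla_sum <- function(data) {
  cols <- nolla_cols()
  check_stage_columns(data, cols, "Nolla")
  mat <- as.matrix(data[cols])
  if (anyNA(mat)) {
    abort_dentalage(
      "incomplete record: missing Nolla stage",
      class = "dentalage_error_incomplete_record"
    )
  }
  ok <- apply(mat, 2, is_nolla_stage)
  if (!all(ok)) {
    abort_dentalage(
      "Nolla stages must lie on the lattice {k, k+.2, k+.5, k+.7, 10}",
      class = "dentalage_error_input"
    )
  }
  dplyr::mutate(tibble::as_tibble(data), nolla_sum = rowSums(mat))
}

#' Demirjian maturity score for one stage vector
#'
#' Low-level scorer: sums the sex-specific self-weighted stage scores of the
#' seven teeth (order 31..37), yielding the 0-100 maturity score.
#'
#' @param stages character vector of 7 Demirjian stages in tooth order 31..37.
#' @param sex `"male"` or `"female"`.
#' @return maturity score in \[0, 100\].
#' @export
demirjian_maturity_stages <- function(stages, sex) {
  sex <- normalize_sex(sex)
  stopifnot(length(stages) == 7, length(sex) == 1)
  stages <- normalize_dem_stage(stages)
  if (anyNA(stages)) {
    abort_dentalage(
      "incomplete record: missing Demirjian stage",
      class = "dentalage_error_incomplete_record"
    )
  }
  tab <- demirjian_score_table(sex)
  key <- paste(tab$tooth, tab$stage)
  idx <- match(paste(fdi_teeth(), stages), key)
  if (anyNA(idx)) {
    abort_dentalage(
      "unknown (tooth, stage) combination in Demirjian lookup",
      class = "dentalage_error_lookup"
    )
  }
  sum(tab$score[idx])
}

#' Demirjian maturity score
#'
#' Adds a `dem_maturity` column: the sex-specific self-weighted Demirjian
#' maturity score (0-100) computed from columns `dem_31`..`dem_37`.
#'
#' @param data a data frame with a `sex` column and columns
#'   `dem_31`..`dem_37` holding stages `"0"`/`"A"`..`"H"`.
#' @return `data` as a tibble with a `dem_maturity` column appended.
#' @export
add_demirjian_maturity <- function(data) {
  cols <- dem_cols()
  check_stage_columns(data, cols, "Demirjian")
  if (!"sex" %in% names(data)) {
    abort_dentalage("missing 'sex' column", class = "dentalage_error_incomplete_record")
  }
  sex <- normalize_sex(data$sex)
  mat <- as.matrix(data[cols])
  score <- vapply(
    seq_len(nrow(data)),
    function(i) demirjian_maturity_stages(mat[i, ], sex[i]),
    numeric(1)
  )
  dplyr::mutate(tibble::as_tibble(data), dem_maturity = score)
}

#' Score a cohort table
#'
#' Convenience verb adding both `nolla_sum` and `dem_maturity` to a cohort
#' table in the package's CSV dialect.
#'
#' @inheritParams add_demirjian_maturity
#' @return a tibble with both score columns appended.
#' @export
score_cohort <- function(data) {
  add_demirjian_maturity(add_nolla_sum(data))
}

#' Convert a score to dental age via norm tables
#'
#' Piecewise-linear interpolation of age against score in the packaged
#' `(age, score)` norm table for the given method and sex. Scores outside the
#' tabulated range clamp to the boundary age and are flagged.
#'
#' @param score numeric vector of maturity (Demirjian) or sum (Nolla) scores.
#' @inheritParams age_norm_table
#' @return a tibble with columns `da_years` and `clamped`.
#' @export
#' @examples
#' score_to_age_lookup(45, method = "nolla", sex = "male")
score_to_age_lookup <- function(score, method = c("demirjian", "nolla"),
                                sex = c("male", "female")) {
  method <- match.arg(method)
  sex <- match.arg(sex)
  norms <- age_norm_table(method, sex)
  lo <- norms$score[1]
  hi <- norms$score[nrow(norms)]
  clamped <- score < lo | score > hi
  da <- approx(
    x = norms$score, y = norms$age, xout = pmin(pmax(score, lo), hi),
    method = "linear", ties = "ordered"
  )$y
  tibble::tibble(da_years = da, clamped = clamped)
}

#' Estimate dental age for a cohort
#'
#' Adds `da_years` (and `da_clamped`) to a scored cohort table using one of
#' the three methods: `"demirjian"` (maturity score through Demirjian norms),
#' `"nolla"` (sum score through Nolla norms), or `"new"` (analytic inversion
#' of a fitted sex-specific quadratic calibration; see
#' [fit_dental_calibration()]).
#'
#' @param data a cohort tibble with `sex` and the relevant score column
#'   (`dem_maturity` or `nolla_sum`); missing score columns are computed from
#'   the stage columns on the fly.
#' @param method `"demirjian"`, `"nolla"` or `"new"`.
#' @param calibration a `dental_calibration` object; required for
#'   `method = "new"`.
#' @return `data` with `da_years` and `da_clamped` columns appended.
#' @export
estimate_dental_age <- function(data, method = c("demirjian", "nolla", "new"),
                                calibration = NULL) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  if (!"sex" %in% names(data)) {
    abort_dentalage("missing 'sex' column", class = "dentalage_error_incomplete_record")
  }
  if (method == "demirjian" && !"dem_maturity" %in% names(data)) {
    data <- add_demirjian_maturity(data)
  }
  if (method %in% c("nolla", "new") && !"nolla_sum" %in% names(data)) {
    data <- add_nolla_sum(data)
  }
  sex <- normalize_sex(data$sex)
  da <- rep(NA_real_, nrow(data))
  clamped <- rep(NA, nrow(data))
  for (sx in unique(sex)) {
    i <- sex == sx
    res <- switch(method,
      demirjian = score_to_age_lookup(data$dem_maturity[i], "demirjian", sx),
      nolla = score_to_age_lookup(data$nolla_sum[i], "nolla", sx),
      new = {
        if (is.null(calibration)) {
          abort_dentalage(
            "method = 'new' requires a fitted calibration",
            class = "dentalage_error_configuration"
          )
        }
        invert_to_age(calibration_model(calibration, sx), data$nolla_sum[i])
      }
    )
    da[i] <- res$da_years
    clamped[i] <- res$clamped
  }
  dplyr::mutate(data, da_years = da, da_clamped = clamped)
}
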