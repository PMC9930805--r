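# Quadratic score-age calibration and analytic inversion ---------------------
#
# The calibration models the Nolla sum score S as a quadratic in chronological
# age x: S = a + b*x + c*x^2 with b > 0 > c over the ages of interest, fitted
# by ordinary least squares per sex. Dental age is read off by inverting the
# fitted parabola analytically on its rising branch (left of the vertex
# -b/(2c)); scores above the curve maximum clamp to the vertex age and the
# result is additionally clamped to the fitted age domain, with flags.

new_quadratic_model <- function(sex, a, b, c, r_squared, age_domain, n,
                                degenerate = FALSE) {
  structure(
    list(
      sex = sex, a = a, b = b, c = c, r_squared = r_squared,
      age_domain = age_domain, n = n, degenerate = degenerate
    ),
    class = "quadratic_model"
  )
}

#' Build a quadratic calibration model from known coefficients
#'
#' Constructs a `quadratic_model` directly from coefficients, e.g. published
#' formulas, without fitting.
#'
#' @param sex `"male"` or `"female"`.
#' @param a,b,c intercept (score), linear (score/year) and quadratic
#'   (score/year^2) coefficients of `score = a + b*age + c*age^2`.
#' @param r_squared coefficient of determination, if known.
#' @param age_domain numeric length-2: the age range the model is valid on.
#' @return a `quadratic_model` object.
#' @export
#' @examples
#' m <- quadratic_model("male", a = 4.916, b = 7.783, c = -0.232)
#' predict_score(m, 10)
quadratic_model <- function(sex, a, b, c, r_squared = NA_real_,
                            age_domain = c(6, 15)) {
  sex <- normalize_sex(sex)
  if (!is.finite(a) || !is.finite(b) || !is.finite(c)) {
    abort_dentalage("coefficients must be finite", class = "dentalage_error_input")
  }
  new_quadratic_model(sex, a, b, c, r_squared, as.numeric(age_domain),
    n = NA_integer_, degenerate = abs(c) < 1e-12
  )
}

#' Fit the quadratic score-age calibration
#'
#' Ordinary least squares of score on (1, age, age^2). `r_squared` is
#' 1 - SSres/SStot; the age domain is set to the input age range. A model with
#' zero score variance or an (essentially) zero quadratic coefficient is
#' flagged `degenerate` and cannot be inverted.
#'
#' @param ca numeric vector of chronological ages (years).
#' @param score numeric vector of sum scores, same length.
#' @param sex optional sex label stored on the model.
#' @return a `quadratic_model` with fields `a`, `b`, `c`, `r_squared`,
#'   `age_domain`, `n`, `degenerate`.
#' @export
#' @examples
#' ages <- seq(6, 15, by = 0.5)
#' fit_quadratic(ages, 4.916 + 7.783 * ages - 0.232 * ages^2, sex = "male")
fit_quadratic <- function(ca, score, sex = NULL) {
  if (length(ca) != length(score)) {
    abort_dentalage("ca and score must have equal length", class = "dentalage_error_input")
  }
  if (any(!is.finite(ca)) || any(!is.finite(score))) {
    abort_dentalage("non-finite values in input", class = "dentalage_error_input")
  }
  if (length(unique(ca)) < 3) {
    abort_dentalage(
      "need at least 3 distinct ages to fit a quadratic",
      class = "dentalage_error_rank_deficiency"
    )
  }
  fit <- lm(score ~ ca + I(ca^2))
  cf <- coef(fit)
  sstot <- sum((score - mean(score))^2)
  ssres <- sum(fit$residuals^2)
  degenerate <- sstot < 1e-12
  r2 <- if (degenerate) NA_real_ else 1 - ssres / sstot
  new_quadratic_model(
    sex = if (is.null(sex)) NA_character_ else normalize_sex(sex),
    a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3]),
    r_squared = r2, age_domain = range(ca), n = length(ca),
    degenerate = degenerate || abs(unname(cf[3])) < 1e-12
  )
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf(
    "<quadratic_model%s>  score = %.3f + %.3f*age %+.3f*age^2\n",
    if (is.na(x$sex)) "" else paste0(" ", x$sex), x$a, x$b, x$c
  ))
  cat(sprintf(
    "  R^2 = %s; age domain [%.2f, %.2f]; vertex at %.2f y%s\n",
    ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
    x$age_domain[1], x$age_domain[2],
    vertex_age(x), if (isTRUE(x$degenerate)) "; DEGENERATE" else ""
  ))
  invisible(x)
}

#' Vertex (curve maximum) age of a calibration model
#'
#' For a concave calibration (`c < 0`) the vertex `-b/(2c)` is the age at
#' which the predicted score peaks; it bounds the analytically invertible
#' domain from above.
#'
#' @param model a `quadratic_model`.
#' @return age in years (`NA` for degenerate models).
#' @export
vertex_age <- function(model) {
  if (isTRUE(model$degenerate) || model$c == 0) {
    return(NA_real_)
  }
  -model$b / (2 * model$c)
}

#' Predict the sum score at given ages
#'
#' Evaluates `a + b*age + c*age^2`. Ages outside the model's age domain are
#' allowed but trigger a warning.
#'
#' @param model a `quadratic_model`.
#' @param ca numeric vector of ages in years.
#' @return numeric vector of predicted scores.
#' @export
predict_score <- function(model, ca) {
  if (any(!is.finite(ca))) {
    abort_dentalage("non-finite age", class = "dentalage_error_input")
  }
  if (any(ca < model$age_domain[1] - 1e-9 | ca > model$age_domain[2] + 1e-9)) {
    warn("predicting outside the model's age domain", class = "dentalage_warning_extrapolation")
  }
  model$a + model$b * ca + model$c * ca^2
}

#' Invert the calibration: dental age from a sum score
#'
#' Solves `a + b*x + c*x^2 = score` for the root on the rising branch (left of
#' the vertex), `x = (-b + sqrt(b^2 - 4c(a - score))) / (2c)` for `c < 0`.
#' Scores above the curve maximum clamp to the vertex age; the result is then
#' clamped to the invertible domain `[age_min, min(age_max, vertex)]`. Both
#' clampings set the `clamped` flag.
#'
#' @param model a `quadratic_model` with negative curvature (`c < 0`).
#' @param score numeric vector of sum scores.
#' @return a tibble with columns `da_years` and `clamped`.
#' @export
#' @examples
#' m <- quadratic_model("male", 4.916, 7.783, -0.232)
#' invert_to_age(m, 59.546) # ~10 years
invert_to_age <- function(model, score) {
  if (isTRUE(model$degenerate) || model$c >= 0) {
    abort_dentalage(
      "inversion requires a non-degenerate concave model (c < 0)",
      class = "dentalage_error_unsupported_curvature"
    )
  }
  if (any(!is.finite(score))) {
    abort_dentalage("non-finite score", class = "dentalage_error_input")
  }
  vx <- vertex_age(model)
  peak <- model$a + model$b * vx + model$c * vx^2
  above <- score > peak
  s <- pmin(score, peak)
  disc <- model$b^2 - 4 * model$c * (model$a - s)
  disc <- pmax(disc, 0) # guard roundoff at the vertex
  if (any(!is.finite(disc))) {
    abort_dentalage("discriminant is not finite", class = "dentalage_error_internal")
  }
  x <- (-model$b + sqrt(disc)) / (2 * model$c)
  upper <- min(model$age_domain[2], vx)
  lower <- model$age_domain[1]
  clamped <- above | x < lower | x > upper
  tibble::tibble(da_years = pmin(pmax(x, lower), upper), clamped = clamped)
}

#' Tabulate a conversion table from a calibration model
#'
#' Builds the age-to-score conversion table on an inclusive uniform age grid.
#' Monotonicity of the scores is verified on the invertible domain.
#'
#' @param model a `quadratic_model`.
#' @param age_min,age_max grid range in years.
#' @param step grid step in years (default 0.1).
#' @return a tibble with columns `age_years` and `score`.
#' @export
build_conversion_table <- function(model, age_min = 6, age_max = 15, step = 0.1) {
  if (!(age_min < age_max) || step <= 0) {
    abort_dentalage("require age_min < age_max and step > 0", class = "dentalage_error_input")
  }
  ages <- seq(age_min, age_max, by = step)
  if (length(ages) == 0) {
    abort_dentalage("empty age grid", class = "dentalage_error_input")
  }
  scores <- suppressWarnings(predict_score(model, ages))
  vx <- vertex_age(model)
  if (is.finite(vx)) {
    inv <- ages <= vx
    if (any(diff(scores[inv]) < -1e-9)) {
      abort_dentalage(
        "conversion table not monotone on the invertible domain",
        class = "dentalage_error_internal"
      )
    }
  }
  tibble::tibble(age_years = ages, score = scores)
}

# --- per-sex calibration container ----------------------------------------

#' Fit sex-specific quadratic calibrations on a cohort
#'
#' Splits the cohort by sex and fits the quadratic sum-score-on-age
#' calibration in each stratum. This is the model-building step of the
#' adapted ("new") dental-age estimation method: fit on a training split,
#' then estimate dental age by analytic inversion with
#' [estimate_dental_age()] `method = "new"`.
#'
#' @param data a cohort tibble with columns `sex`, `ca_years` and `nolla_sum`
#'   (computed from stage columns if absent).
#' @return a `dental_calibration` object: a list of `quadratic_model`s keyed
#'   by sex.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' cal <- fit_dental_calibration(cohort)
#' tidy(cal)
fit_dental_calibration <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"nolla_sum" %in% names(data)) data <- add_nolla_sum(data)
  if (!all(c("sex", "ca_years") %in% names(data))) {
    abort_dentalage("need 'sex' and 'ca_years' columns", class = "dentalage_error_incomplete_record")
  }
  sex <- normalize_sex(data$sex)
  models <- lapply(c("male", "female"), function(sx) {
    i <- sex == sx
    if (!any(i)) {
      return(NULL)
    }
    fit_quadratic(data$ca_years[i], data$nolla_sum[i], sex = sx)
  })
  names(models) <- c("male", "female")
  structure(models[!vapply(models, is.null, logical(1))],
    class = "dental_calibration"
  )
}

calibration_model <- function(calibration, sex) {
  stopifnot(inherits(calibration, "dental_calibration"))
  m <- calibration[[normalize_sex(sex)]]
  if (is.null(m)) {
    abort_dentalage(
      sprintf("no calibration model for sex '%s'", sex),
      class = "dentalage_error_configuration"
    )
  }
  m
}

#' @export
print.dental_calibration <- function(x, ...) {
  cat("<dental_calibration>\n")
  for (m in x) print(m)
  invisible(x)
}

#' Compare polynomial curve families by R-squared
#'
#' Convenience screen over linear, quadratic and cubic fits of score on age,
#' reporting each family's R-squared. Because the families are nested, R^2 is
#' non-decreasing with degree; the quadratic is the package's calibration
#' default.
#'
#' @inheritParams fit_quadratic
#' @return a tibble with columns `family`, `degree`, `r_squared`.
#' @export
compare_curve_families <- function(ca, score) {
  if (length(unique(ca)) < 4) {
    abort_dentalage("need at least 4 distinct ages", class = "dentalage_error_rank_deficiency")
  }
  sstot <- sum((score - mean(score))^2)
  r2 <- vapply(1:3, function(d) {
    fit <- lm(score ~ poly(ca, d, raw = TRUE))
    1 - sum(fit$residuals^2) / sstot
  }, numeric(1))
  tibble::tibble(
    family = c("linear", "quadratic", "cubic"),
    degree = 1:3, r_squared = r2
  )
}

# --- broom-style methods ----------------------------------------------------

#' Tidy a quadratic calibration model
#'
#' @param x a `quadratic_model`.
#' @param ... unused.
#' @return a tibble with one row per coefficient (`term`, `estimate`).
#' @method tidy quadratic_model
#' @export
tidy.quadratic_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "age", "age^2"),
    estimate = c(x$a, x$b, x$c)
  )
}

#' Glance at a quadratic calibration model
#'
#' @inheritParams tidy.quadratic_model
#' @return a one-row tibble with `r.squared`, `nobs`, the age domain, the
#'   vertex age and the degeneracy flag.
#' @method glance quadratic_model
#' @export
glance.quadratic_model <- function(x, ...) {
  tibble::tibble(
    sex = x$sex, r.squared = x$r_squared, nobs = x$n,
    age_min = x$age_domain[1], age_max = x$age_domain[2],
    vertex = vertex_age(x), degenerate = x$degenerate
  )
}

#' Tidy a sex-specific calibration
#'
#' @param x a `dental_calibration`.
#' @param ... unused.
#' @return a tibble with columns `sex`, `term`, `estimate`.
#' @method tidy dental_calibration
#' @export
tidy.dental_calibration <- function(x, ...) {
  purrr::map_dfr(x, function(m) {
    dplyr::mutate(tidy.quadratic_model(m), sex = m$sex, .before = 1)
  })
}

#' Glance at a sex-specific calibration
#'
#' @inheritParams tidy.dental_calibration
#' @return one row per sex, as [glance.quadratic_model()].
#' @method glance dental_calibration
#' @export
glance.dental_calibration <- function(x, ...) {
  purrr::map_dfr(x, glance.quadratic_model)
}

# --- JSON round-trip --------------------------------------------------------

#' Write / read a calibration as JSON
#'
#' Serializes each sex's model as
#' `{sex, a, b, c, r_squared, age_min, age_max, source}`.
#'
#' @param calibration a `dental_calibration`.
#' @param path file path.
#' @param source free-text provenance string stored in the file.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a `dental_calibration`.
#' @export
write_calibration <- function(calibration, path, source = "dentalage") {
  stopifnot(inherits(calibration, "dental_calibration"))
  payload <- lapply(calibration, function(m) {
    list(
      sex = m$sex, a = m$a, b = m$b, c = m$c, r_squared = m$r_squared,
      age_min = m$age_domain[1], age_max = m$age_domain[2], source = source
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  models <- lapply(payload, function(p) {
    quadratic_model(
      sex = p$sex, a = p$a, b = p$b, c = p$c,
      r_squared = p$r_squared %||% NA_real_,
      age_domain = c(p$age_min, p$age_max)
    )
  })
  names(models) <- vapply(models, function(m) m$sex, character(1))
  structure(models, class = "dental_calibration")
}
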