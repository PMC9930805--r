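# Shared fixtures and independent oracles for the test suite.

# Published sex-specific quadratic coefficients used throughout as ground truth
# for recovery tests: score = a + b*age + c*age^2.
male_coefs <- list(a = 4.916, b = 7.783, c = -0.232)
female_coefs <- list(a = -2.751, b = 9.785, c = -0.331)

quad_eval <- function(cf, x) cf$a + cf$b * x + cf$c * x^2

male_model <- function() quadratic_model("male", male_coefs$a, male_coefs$b, male_coefs$c)
female_model <- function() quadratic_model("female", female_coefs$a, female_coefs$b, female_coefs$c)

# A tiny valid cohort row with all stage columns.
stage_row <- function(subject_id = "S1", sex = "male", ca_years = 10,
                      nolla = rep(5, 7), dem = rep("D", 7)) {
  row <- tibble::tibble(subject_id = subject_id, sex = sex, ca_years = ca_years)
  for (i in seq_along(31:37)) {
    row[[paste0("nolla_3", i)]] <- nolla[i]
    row[[paste0("dem_3", i)]] <- dem[i]
  }
  row
}

# Independent oracle: exact two-sided signed-rank p by enumerating all 2^n
# sign patterns (n <= ~12). Mid-ranks for ties, zeros assumed already dropped.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(pos) sum(ranks[as.logical(pos)]))
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Independent oracle: dental age by bisection of the calibration curve on the
# rising branch.
bisect_invert <- function(model, score, lo = NULL, hi = NULL, tol = 1e-12) {
  lo <- lo %||% (model$age_domain[1] - 5)
  hi <- hi %||% vertex_age(model)
  f <- function(x) model$a + model$b * x + model$c * x^2 - score
  stopifnot(f(lo) < 0, f(hi) >= 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

`%||%` <- function(x, y) if (is.null(x)) y else x
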