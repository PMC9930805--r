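# Accuracy-evaluation protocol ------------------------------------------------
#
# Agreement between estimated dental age (DA) and chronological age (CA) is
# summarized per 1-year age group and sex, and in total, by:
#   MD  = mean(DA - CA)   (> 0: overestimation of age)
#   MAD = mean(|DA - CA|)
# with SDs, a t-based 95% CI for MD, and a paired location test gated on a
# Kolmogorov-Smirnov normality check of the differences (paired t if normal,
# Wilcoxon signed-rank otherwise). Observer reproducibility of the staging is
# quantified with unweighted Cohen's kappa on pooled (subject, tooth) ratings.

#' Age-group labels
#'
#' The nine 1-year bins partitioning (6, 15] years, labelled
#' `"6.01-7.00"` .. `"14.01-15.00"`.
#'
#' @return character vector of the nine labels, in order.
#' @export
age_group_levels <- function() {
  sprintf("%d.01-%d.00", 6:14, 7:15)
}

#' Assign chronological ages to 1-year groups
#'
#' Ages are rounded half-up at two decimals, then binned into the half-open
#' intervals (x.00, (x+1).00] so that e.g. 7.00 falls in "6.01-7.00" and
#' 7.005 (rounded to 7.01) in "7.01-8.00".
#'
#' @param ca_years numeric vector of ages in (6, 15].
#' @return factor with levels [age_group_levels()].
#' @export
#' @examples
#' assign_age_group(c(6.74, 7.00, 7.005))
assign_age_group <- function(ca_years) {
  r <- round_half_up(ca_years, 2)
  if (any(r <= 6 | r > 15)) {
    abort_dentalage(
      "age outside the supported range (6, 15]",
      class = "dentalage_error_out_of_range"
    )
  }
  idx <- ceiling(r - 1e-9) - 6
  idx[idx < 1] <- 1
  factor(age_group_levels()[idx], levels = age_group_levels())
}

#' Accuracy statistics for paired CA/DA values
#'
#' Computes n, mean CA/DA with SDs, MD = mean(DA - CA) with SD and its
#' t-based 95% CI, and MAD = mean(|DA - CA|) with SD. MD > 0 indicates
#' overestimation of chronological age.
#'
#' @param ca,da numeric vectors of chronological and dental ages (years),
#'   equal length, n >= 2.
#' @return a one-row tibble with columns `n`, `mean_ca`, `sd_ca`, `mean_da`,
#'   `sd_da`, `md`, `sd_md`, `ci_lo`, `ci_hi`, `mad`, `sd_mad`.
#' @export
#' @examples
#' accuracy_stats(c(10, 10), c(11, 9)) # MD 0, MAD 1
accuracy_stats <- function(ca, da) {
  if (length(ca) != length(da)) {
    abort_dentalage("ca and da must have equal length", class = "dentalage_error_input")
  }
  n <- length(ca)
  if (n < 2) {
    abort_dentalage(
      "need at least 2 pairs (SD undefined otherwise)",
      class = "dentalage_error_insufficient_data"
    )
  }
  d <- da - ca
  md <- mean(d)
  sd_md <- sd(d)
  half <- qt(0.975, n - 1) * sd_md / sqrt(n)
  tibble::tibble(
    n = n,
    mean_ca = mean(ca), sd_ca = sd(ca),
    mean_da = mean(da), sd_da = sd(da),
    md = md, sd_md = sd_md,
    ci_lo = md - half, ci_hi = md + half,
    mad = mean(abs(d)), sd_mad = sd(abs(d))
  )
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the differences against a normal distribution with
#' mean and SD estimated from the sample, asymptotic p-value. Estimating the
#' parameters from the data makes the test conservative (the Lilliefors
#' caveat); this matches common applied practice and is documented as an
#' approximation. A zero-variance sample is flagged degenerate and treated as
#' non-normal downstream.
#'
#' @param x numeric vector of differences (n >= 4 for a meaningful test).
#' @return a list with `p_value`, `statistic` and `degenerate`.
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4 || sd(x) < 1e-12) {
    return(list(p_value = NA_real_, statistic = NA_real_, degenerate = TRUE))
  }
  ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x), exact = FALSE))
  list(p_value = unname(ks$p.value), statistic = unname(ks$statistic), degenerate = FALSE)
}

# Exact distribution of the signed-rank statistic W+ for given (mid-)ranks,
# by convolution on doubled ranks (integers even with ties). Returns
# P(W+ = s/2) indexed by s = 0..sum(2r).
signed_rank_distribution <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  p <- numeric(total + 1)
  p[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), p[seq_len(total + 1 - r)])
    p <- (p + shifted) / 2
  }
  p
}

signed_rank_exact_p <- function(w_plus, ranks) {
  dist <- signed_rank_distribution(ranks)
  s <- round(2 * w_plus)
  support <- seq_along(dist) - 1
  lower <- sum(dist[support <= s + 1e-9])
  upper <- sum(dist[support >= s - 1e-9])
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon signed-rank test of paired differences
#'
#' Zero differences are dropped; ties in the absolute differences receive
#' average (mid-)ranks. The two-sided p-value is exact (full null distribution
#' of the signed-rank sum, valid under ties) for n <= `exact_max` non-zero
#' differences, and a normal approximation with tie-corrected variance above.
#' An all-zero sample returns p = 1 with a flag.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max largest n for which the exact distribution is used
#'   (default 25).
#' @return a list with `p_value`, `statistic` (W+), `n_nonzero`, `exact` and
#'   `degenerate`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(-2, -1, 1, 2))$p_value # exactly 1
wilcoxon_signed_rank <- function(d, exact_max = 25) {
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(
      p_value = 1, statistic = NA_real_, n_nonzero = 0L,
      exact = TRUE, degenerate = TRUE
    ))
  }
  ranks <- rank(abs(d)) # mid-ranks for ties
  w_plus <- sum(ranks[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(w_plus, ranks)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(ranks)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  list(
    p_value = p, statistic = w_plus, n_nonzero = as.integer(n),
    exact = exact, degenerate = FALSE
  )
}

#' Normality-gated paired location test
#'
#' Tests whether the paired differences are centred at zero. If the KS
#' normality check accepts normality (p > 0.05) a paired t-test is used;
#' otherwise (including degenerate or short samples) the Wilcoxon signed-rank
#' test. All-zero differences return p = 1 by convention, flagged.
#'
#' @inheritParams wilcoxon_signed_rank
#' @return a list with `p_value`, `test_used` (`"paired_t"` or
#'   `"wilcoxon"`) and `degenerate`.
#' @export
paired_location_test <- function(d) {
  d <- d[is.finite(d)]
  if (length(d) < 2) {
    abort_dentalage("need at least 2 differences", class = "dentalage_error_insufficient_data")
  }
  if (all(d == 0)) {
    return(list(p_value = 1, test_used = "wilcoxon", degenerate = TRUE))
  }
  norm <- normality_test(d)
  if (!norm$degenerate && norm$p_value > 0.05) {
    tt <- t.test(d)
    list(p_value = unname(tt$p.value), test_used = "paired_t", degenerate = FALSE)
  } else {
    w <- wilcoxon_signed_rank(d)
    list(p_value = w$p_value, test_used = "wilcoxon", degenerate = w$degenerate)
  }
}

#' Cohen's kappa for two raters
#'
#' Unweighted chance-corrected agreement `(p_o - p_e)/(1 - p_e)` for two
#' equal-length categorical rating sequences over a shared vocabulary (e.g.
#' all subject-by-tooth stage assignments pooled into one sequence per rater).
#' If both raters are constant and identical (`p_e = 1`) kappa is undefined
#' and `NA` is returned with a warning.
#'
#' @param ratings_a,ratings_b vectors of categorical ratings, equal length.
#' @return kappa in \[-1, 1\], or `NA` if undefined.
#' @export
#' @examples
#' cohens_kappa(rep(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1), 1), c(0, 0, 0, 0, 1, 0, 1, 1, 1, 1))
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    abort_dentalage("rating sequences must have equal length", class = "dentalage_error_input")
  }
  a <- as.character(ratings_a)
  b <- as.character(ratings_b)
  lev <- sort(union(unique(a), unique(b)))
  tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    warn("kappa undefined: both raters constant and identical", class = "dentalage_warning_degenerate")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Evaluate a dental-age estimation method on a cohort
#'
#' Produces the standard accuracy report: one row per sex and 1-year age
#' group, one total row per sex, and a grand-total row, each with mean CA/DA,
#' MD (SD) and its 95% CI, MAD (SD), and the p-value of the normality-gated
#' paired test. Empty groups are omitted with a warning.
#'
#' @param data a cohort tibble with columns `sex`, `ca_years` and `da_years`
#'   (e.g. from [estimate_dental_age()]).
#' @return a tibble with columns `sex`, `group`, and the columns of
#'   [accuracy_stats()] plus `p_value` and `test_used`. Total rows carry
#'   `group = "total"`; the grand total has `sex = "total"`.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' cal <- fit_dental_calibration(cohort)
#' cohort |>
#'   estimate_dental_age("new", cal) |>
#'   evaluate_method()
evaluate_method <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("sex", "ca_years", "da_years")
  if (!all(need %in% names(data))) {
    abort_dentalage(
      sprintf("need columns: %s", paste(need, collapse = ", ")),
      class = "dentalage_error_incomplete_record"
    )
  }
  data$sex <- normalize_sex(data$sex)
  data$group <- assign_age_group(data$ca_years)

  one_report <- function(df, sex_label, group_label) {
    stats <- accuracy_stats(df$ca_years, df$da_years)
    test <- paired_location_test(df$da_years - df$ca_years)
    dplyr::mutate(stats,
      sex = sex_label, group = group_label,
      p_value = test$p_value, test_used = test$test_used,
      .before = 1
    )
  }

  rows <- list()
  for (sx in intersect(c("male", "female"), unique(data$sex))) {
    dsx <- data[data$sex == sx, ]
    for (g in age_group_levels()) {
      dg <- dsx[dsx$group == g, ]
      if (nrow(dg) == 0) {
        warn(sprintf("empty group %s/%s omitted", sx, g), class = "dentalage_warning_empty_group")
        next
      }
      rows[[length(rows) + 1]] <- one_report(dg, sx, g)
    }
    rows[[length(rows) + 1]] <- one_report(dsx, sx, "total")
  }
  rows[[length(rows) + 1]] <- one_report(data, "total", "total")
  dplyr::bind_rows(rows)
}
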