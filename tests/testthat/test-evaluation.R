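test_that("ages bin into the nine 1-year groups with half-up rounding", {
  expect_equal(as.character(assign_age_group(6.74)), "6.01-7.00")
  expect_equal(as.character(assign_age_group(7.00)), "6.01-7.00")
  expect_equal(as.character(assign_age_group(7.005)), "7.01-8.00")
  expect_equal(as.character(assign_age_group(15)), "14.01-15.00")
  expect_equal(as.character(assign_age_group(6.01)), "6.01-7.00")
  expect_error(assign_age_group(5.9), class = "dentalage_error_out_of_range")
  expect_error(assign_age_group(15.01), class = "dentalage_error_out_of_range")
  expect_length(age_group_levels(), 9)
})

test_that("accuracy statistics follow their definitions", {
  # MD 0 with MAD 1: opposite one-year errors
  st <- accuracy_stats(c(10, 10), c(11, 9))
  expect_equal(st$md, 0)
  expect_equal(st$mad, 1)
  # perfect agreement
  st0 <- accuracy_stats(c(8, 9, 10), c(8, 9, 10))
  expect_equal(st0$md, 0)
  expect_equal(st0$mad, 0)
  # t-quantile CI of MD
  ca <- c(6.2, 6.5, 6.8, 7.0)
  da <- c(6.9, 7.1, 7.4, 7.6)
  st2 <- accuracy_stats(ca, da)
  d <- da - ca
  expect_equal(st2$md, mean(d))
  expect_equal(st2$ci_lo, mean(d) - qt(0.975, 3) * sd(d) / 2)
  expect_equal(st2$ci_hi, mean(d) + qt(0.975, 3) * sd(d) / 2)
  expect_error(accuracy_stats(1, 2), class = "dentalage_error_insufficient_data")
})

test_that("MAD dominates |MD|, with equality iff one sign", {
  set.seed(23)
  for (i in 1:30) {
    d <- rnorm(20)
    st <- accuracy_stats(rep(10, 20), 10 + d)
    expect_gte(st$mad + 1e-12, abs(st$md))
    if (all(d > 0) || all(d < 0)) expect_equal(st$mad, abs(st$md))
  }
  same_sign <- accuracy_stats(rep(10, 5), 10 + c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(same_sign$mad, same_sign$md)
})

test_that("KS normality check accepts normal and rejects bimodal samples", {
  set.seed(31)
  norm_sample <- rnorm(100)
  res <- normality_test(norm_sample)
  expect_gt(res$p_value, 0.05)
  # oracle: identical call through stats::ks.test
  oracle <- suppressWarnings(
    ks.test(norm_sample, "pnorm", mean(norm_sample), sd(norm_sample), exact = FALSE)
  )
  expect_equal(res$p_value, unname(oracle$p.value))
  bimodal <- rep(c(-1, 1), each = 50)
  expect_lt(normality_test(bimodal)$p_value, 0.05)
  expect_true(normality_test(rep(0.3, 10))$degenerate)
})

test_that("exact signed-rank p matches full sign-pattern enumeration", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), 1) # rounding induces ties and zeros
    if (all(d == 0)) d[1] <- 0.5
    ours <- wilcoxon_signed_rank(d)
    expect_true(ours$exact)
    expect_equal(ours$p_value, enumerate_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("signed-rank edge cases take their closed-form values", {
  # balanced ranks: exact two-sided p = 1
  expect_equal(wilcoxon_signed_rank(c(-2, -1, 1, 2))$p_value, 1)
  # all positive, n = 10: smallest attainable two-sided p = 2/2^10
  expect_equal(wilcoxon_signed_rank(rep(0.5, 10))$p_value, 2 / 1024)
  # all zeros: p = 1 by convention, flagged
  allz <- wilcoxon_signed_rank(rep(0, 6))
  expect_equal(allz$p_value, 1)
  expect_true(allz$degenerate)
})

test_that("exact signed-rank agrees with wilcox.test when ties are absent", {
  set.seed(43)
  for (i in 1:10) {
    d <- rnorm(12)
    ours <- wilcoxon_signed_rank(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("large-sample signed-rank uses the tie-corrected normal approximation", {
  set.seed(47)
  d <- round(rnorm(60, 0.1), 1)
  d <- d[d != 0]
  ours <- wilcoxon_signed_rank(d)
  expect_false(ours$exact)
  ref <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = FALSE))
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("the normality gate switches the paired test", {
  set.seed(53)
  # clearly normal differences -> paired t
  d_norm <- rnorm(50, 0.2, 1)
  res_t <- paired_location_test(d_norm)
  expect_equal(res_t$test_used, "paired_t")
  expect_equal(res_t$p_value, unname(t.test(d_norm)$p.value))
  # strongly bimodal differences -> wilcoxon branch
  d_bim <- rep(c(-1, 1.01), each = 30) + rnorm(60, 0, 0.01)
  res_w <- paired_location_test(d_bim)
  expect_equal(res_w$test_used, "wilcoxon")
  # symmetric +/-1 differences: t branch, t = 0, p = 1
  expect_equal(paired_location_test(c(-1, 1))$p_value, 1)
  # all-zero differences: p = 1 by convention
  expect_equal(paired_location_test(rep(0, 5))$p_value, 1)
})

test_that("Cohen's kappa matches hand arithmetic and a reference implementation", {
  expect_equal(cohens_kappa(c("A", "B", "A"), c("A", "B", "A")), 1)
  # 2x2 table a=4, b=1, c=1, d=4: p_o = 0.8, p_e = 0.5, kappa = 0.6
  a <- c(rep("x", 5), rep("y", 5))
  b <- c(rep("x", 4), "y", "x", rep("y", 4))
  expect_equal(cohens_kappa(a, b), 0.6)
  # dual route: e1071's kappa on a random contingency table
  set.seed(61)
  r1 <- sample(LETTERS[1:4], 200, replace = TRUE)
  r2 <- ifelse(runif(200) < 0.6, r1, sample(LETTERS[1:4], 200, replace = TRUE))
  expect_equal(
    cohens_kappa(r1, r2),
    e1071::classAgreement(table(r1, r2))$kappa,
    tolerance = 1e-12
  )
  # independence: kappa ~ 0
  r3 <- sample(LETTERS[1:4], 5000, replace = TRUE)
  r4 <- sample(LETTERS[1:4], 5000, replace = TRUE)
  expect_lt(abs(cohens_kappa(r3, r4)), 0.05)
  # relabelling invariance
  relabel <- c(A = "w", B = "x", C = "y", D = "z")
  expect_equal(cohens_kappa(r1, r2), cohens_kappa(relabel[r1], relabel[r2]))
  # degenerate identical constant raters
  expect_warning(k <- cohens_kappa(rep("A", 5), rep("A", 5)))
  expect_true(is.na(k))
})

test_that("evaluate_method reports per group, per sex and in total", {
  cohort <- simulate_cohort(seed = 71)
  # constant +0.5 shift: every MD and MAD is 0.5
  shifted <- dplyr::mutate(cohort, da_years = ca_years + 0.5)
  rep1 <- evaluate_method(shifted)
  expect_equal(nrow(rep1), 9 * 2 + 2 + 1)
  expect_true(all(abs(rep1$md - 0.5) < 1e-12))
  expect_true(all(abs(rep1$mad - 0.5) < 1e-12))
  # DA == CA: all-zero report, p = 1 everywhere
  perfect <- dplyr::mutate(cohort, da_years = ca_years)
  rep2 <- evaluate_method(perfect)
  expect_true(all(rep2$md == 0))
  expect_true(all(rep2$p_value == 1))
  # grand-total MD equals mean(DA) - mean(CA)
  est <- dplyr::mutate(cohort, da_years = ca_years + rnorm(nrow(cohort), 0, 0.5))
  rep3 <- evaluate_method(est)
  grand <- rep3[rep3$sex == "total", ]
  expect_equal(grand$md, mean(est$da_years) - mean(est$ca_years))
  # grand-total MD is the count-weighted mean of per-group MDs
  groups <- rep3[rep3$sex != "total" & rep3$group != "total", ]
  expect_equal(grand$md, sum(groups$md * groups$n) / sum(groups$n))
  expect_equal(sum(groups$n), nrow(cohort))
})

test_that("empty groups are omitted with a warning", {
  cohort <- simulate_cohort(seed = 73)
  small <- dplyr::filter(
    dplyr::mutate(cohort, da_years = ca_years),
    !(sex == "male" & age_group == "8.01-9.00")
  )
  expect_warning(
    rep <- evaluate_method(small),
    class = "dentalage_warning_empty_group"
  )
  expect_equal(nrow(rep), 9 * 2 + 2 + 1 - 1)
})
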