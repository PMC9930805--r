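# Builds the packaged lookup tables under inst/extdata/.
#
# 1. demirjian_scores_{male,female}.csv — the classical seven-tooth
#    self-weighted stage scores (left mandibular teeth, FDI 31-37). Each sex's
#    stage-H row sums to exactly 100.0 (the published normalization; asserted
#    below). Stages preceding a tooth's first tabulated stage score 0.
# 2. {demirjian,nolla}_age_norms_{male,female}_synthetic.csv — SYNTHETIC
#    score-to-age conversion norms, constructed so that on cohorts generated by
#    simulate_cohort() the classical Nolla lookup underestimates chronological
#    age by ~0.40 y and the Demirjian lookup overestimates it by ~0.24 y,
#    emulating the population-mismatch biases such studies report. They are not
#    the historical norm tables.
# 3. checksums.csv — md5 manifest validated at load time.
#
# Run from the package root with the package loadable (pkgload/devtools).

library(tibble)
library(dplyr)
library(readr)
devtools::load_all(".", quiet = TRUE)

out <- "inst/extdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

stages <- c("0", LETTERS[1:8])

row_scores <- function(tooth, vals) {
  # vals: named vector for tabulated stages; earlier stages get 0
  full <- setNames(numeric(9), stages)
  full[names(vals)] <- vals
  first <- match(names(vals)[1], stages)
  if (first > 1) full[seq_len(first - 1)] <- 0
  tibble(tooth = tooth, stage = stages, score = unname(full))
}

male <- bind_rows(
  row_scores(37, c("0" = 0, A = 2.1, B = 3.5, C = 5.9, D = 10.1, E = 12.5, F = 13.2, G = 13.6, H = 15.4)),
  row_scores(36, c(C = 0, D = 8.0, E = 9.6, F = 12.3, G = 17.0, H = 19.3)),
  row_scores(35, c("0" = 0, A = 1.7, B = 3.1, C = 5.4, D = 9.7, E = 12.0, F = 12.8, G = 13.2, H = 14.4)),
  row_scores(34, c(B = 0, C = 3.4, D = 7.0, E = 11.0, F = 12.3, G = 12.7, H = 13.5)),
  row_scores(33, c(C = 0, D = 3.5, E = 7.9, F = 10.0, G = 11.0, H = 11.9)),
  row_scores(32, c(C = 0, D = 3.2, E = 5.2, F = 7.8, G = 11.7, H = 13.7)),
  row_scores(31, c(D = 0, E = 1.9, F = 4.1, G = 8.2, H = 11.8))
)

female <- bind_rows(
  row_scores(37, c("0" = 0, A = 2.7, B = 3.9, C = 6.9, D = 11.1, E = 13.5, F = 14.2, G = 14.5, H = 15.6)),
  row_scores(36, c(C = 0, D = 4.5, E = 6.2, F = 9.0, G = 14.0, H = 16.2)),
  row_scores(35, c("0" = 0, A = 1.8, B = 3.4, C = 6.5, D = 10.6, E = 12.7, F = 13.5, G = 13.8, H = 14.6)),
  row_scores(34, c(B = 0, C = 3.7, D = 7.5, E = 11.8, F = 13.1, G = 13.4, H = 14.1)),
  row_scores(33, c(C = 0, D = 3.8, E = 7.3, F = 10.3, G = 11.6, H = 12.4)),
  row_scores(32, c(C = 0, D = 3.2, E = 5.6, F = 8.0, G = 12.2, H = 14.2)),
  row_scores(31, c(D = 0, E = 2.4, F = 5.1, G = 9.3, H = 12.9))
)

stopifnot(
  abs(sum(male$score[male$stage == "H"]) - 100) < 1e-9,
  abs(sum(female$score[female$stage == "H"]) - 100) < 1e-9
)

write_csv(male, file.path(out, "demirjian_scores_male.csv"))
write_csv(female, file.path(out, "demirjian_scores_female.csv"))

# interim manifest so the package's checksum-validated loaders work while the
# norm files are being generated below
score_files <- c("demirjian_scores_male.csv", "demirjian_scores_female.csv")
write_csv(
  tibble(file = score_files, md5 = unname(tools::md5sum(file.path(out, score_files)))),
  file.path(out, "checksums.csv")
)

# --- synthetic score->age norms ------------------------------------------

coefs <- default_coefficients()
quad <- function(sex, x) {
  cf <- coefs[coefs$sex == sex, ]
  cf$a + cf$b * x + cf$c * x^2
}
vertex <- function(sex) {
  cf <- coefs[coefs$sex == sex, ]
  -cf$b / (2 * cf$c)
}

# Nolla norms: expected sum at age x equals the generating curve at x + 0.40,
# so norm-lookup of a generated score reads ~0.40 y younger than truth.
nolla_shift <- 0.40
for (sx in c("male", "female")) {
  upper <- min(16, vertex(sx) - nolla_shift - 0.2)
  ages <- seq(3, upper, by = 0.2)
  norms <- tibble(age = round(ages, 2), score = round(quad(sx, ages + nolla_shift), 3))
  stopifnot(all(diff(norms$score) > 0))
  write_csv(norms, file.path(out, sprintf("nolla_age_norms_%s_synthetic.csv", sx)))
}

# Demirjian norms: the mean maturity trajectory induced by the generator
# pipeline (quadratic sum -> jittered allocation -> lattice snap -> stage
# letters -> self-weighted maturity), shifted -0.24 y so lookups read ~0.24 y
# older than truth. Averaging over the generator's per-tooth jitter smooths
# the stage-transition staircase of the noiseless curve; the result is made
# strictly increasing before writing.
dem_shift <- 0.24
n_rep <- 400
induced_maturity <- function(sex, ages) {
  target <- pmin(pmax(quad(sex, ages), 0), 70)
  vapply(seq_along(ages), function(i) {
    mean(vapply(seq_len(n_rep), function(r) {
      nolla <- allocate_tooth_stages(target[i], jitter_sd = 0.3)
      demirjian_maturity_stages(derive_demirjian_stages(nolla), sex)
    }, numeric(1)))
  }, numeric(1))
}
set.seed(20260923)
for (sx in c("male", "female")) {
  upper <- min(16, vertex(sx) + dem_shift - 0.1)
  ages <- seq(3.5, upper, by = 0.1)
  score <- induced_maturity(sx, ages - dem_shift)
  keep <- c(TRUE, diff(cummax(score)) > 1e-6)
  score <- cummax(score)[keep]
  norms <- tibble(age = round(ages[keep], 3), score = round(score, 3))
  stopifnot(all(diff(norms$score) > 0), all(diff(norms$age) > 0))
  write_csv(norms, file.path(out, sprintf("demirjian_age_norms_%s_synthetic.csv", sx)))
}

files <- c(
  "demirjian_scores_male.csv", "demirjian_scores_female.csv",
  "nolla_age_norms_male_synthetic.csv", "nolla_age_norms_female_synthetic.csv",
  "demirjian_age_norms_male_synthetic.csv", "demirjian_age_norms_female_synthetic.csv"
)
manifest <- tibble(file = files, md5 = unname(tools::md5sum(file.path(out, files))))
write_csv(manifest, file.path(out, "checksums.csv"))
message("lookup tables written to ", out)
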