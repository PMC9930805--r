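# Synthetic cohort generator --------------------------------------------------
#
# Emulates an age- and sex-stratified radiographic study: 535 children aged
# 6-15 in nine 1-year bins per sex (train/test cells in a ~7:3 ratio), whose
# latent Nolla sum scores follow sex-specific quadratics in age plus Gaussian
# noise. Per-tooth Nolla stages are realized by allocating the sum across the
# seven teeth and snapping to the Nolla reading lattice; companion Demirjian
# letters are derived from per-tooth maturity fractions. The generator targets
# the statistical structure the downstream analysis assumes, not tooth
# biology; in particular the Nolla-to-Demirjian mapping is an affine
# convenience real staging systems do not obey.

#' Default stratified study design
#'
#' The default cohort design: nine 1-year age bins per sex with a ~7:3
#' train/test split per cell. Totals: 358 training (180 male, 178 female),
#' 177 testing (89 male, 88 female), 535 overall. The male and female
#' 6.01-7.00 cells are slightly smaller (20/9 and 18/8).
#'
#' @return a tibble with columns `age_group`, `lower`, `upper`, `sex`,
#'   `n_train`, `n_test`.
#' @export
#' @examples
#' sum(cohort_design()$n_train) + sum(cohort_design()$n_test) # 535
cohort_design <- function() {
  groups <- age_group_levels()
  grid <- tidyr::expand_grid(
    age_group = groups,
    sex = c("male", "female")
  )
  grid$lower <- rep(6:14, each = 2)
  grid$upper <- grid$lower + 1
  grid$n_train <- ifelse(grid$age_group == "6.01-7.00" & grid$sex == "female", 18, 20)
  grid$n_test <- dplyr::case_when(
    grid$age_group == "6.01-7.00" & grid$sex == "male" ~ 9L,
    grid$age_group == "6.01-7.00" & grid$sex == "female" ~ 8L,
    TRUE ~ 10L
  )
  tibble::as_tibble(grid[c("age_group", "lower", "upper", "sex", "n_train", "n_test")])
}

validate_design <- function(design) {
  need <- c("age_group", "lower", "upper", "sex", "n_train", "n_test")
  if (!all(need %in% names(design))) {
    abort_dentalage("invalid design: missing columns", class = "dentalage_error_configuration")
  }
  if (any(design$n_train < 0) || any(design$n_test < 0)) {
    abort_dentalage("cell counts must be >= 0", class = "dentalage_error_configuration")
  }
  invisible(design)
}

#' Published calibration coefficients
#'
#' The sex-specific quadratic coefficients of the adapted Nolla-sum
#' calibration (`score = a + b*age + c*age^2`) used as the generator's
#' defaults: males (4.916, 7.783, -0.232), females (-2.751, 9.785, -0.331).
#'
#' @return a tibble with columns `sex`, `a`, `b`, `c`.
#' @export
default_coefficients <- function() {
  tibble::tibble(
    sex = c("male", "female"),
    a = c(4.916, -2.751),
    b = c(7.783, 9.785),
    c = c(-0.232, -0.331)
  )
}

#' Draw stratified ages
#'
#' For each design cell, draws its `n_train + n_test` ages uniformly within
#' the cell's half-open interval (lower + 0.01, upper], rounded half-up to
#' two decimals (the resolution of the age-group labels).
#'
#' @param design a design tibble as from [cohort_design()].
#' @param seed optional integer seed (uses the current RNG stream if `NULL`).
#' @return a tibble with columns `sex`, `age_group`, `ca_years`.
#' @export
draw_ages <- function(design = cohort_design(), seed = NULL) {
  validate_design(design)
  with_seed(seed, {
    purrr::pmap_dfr(design, function(age_group, lower, upper, sex, n_train, n_test) {
      n <- n_train + n_test
      ca <- round_half_up(runif(n, min = lower + 0.01, max = upper), 2)
      tibble::tibble(sex = sex, age_group = age_group, ca_years = ca)
    })
  })
}

#' Latent Nolla sum score at a given age
#'
#' Evaluates the sex-specific quadratic and adds Gaussian score noise,
#' clamping the result to the attainable range \[0, 70\].
#'
#' @param ca numeric vector of ages in years.
#' @param sex a single sex label, or a vector matching `ca`.
#' @param coefficients tibble of per-sex `(a, b, c)`; defaults to
#'   [default_coefficients()].
#' @param noise_sd SD of the additive score noise, in score units.
#' @inheritParams draw_ages
#' @return numeric vector of latent sum scores in \[0, 70\].
#' @export
latent_sum_score <- function(ca, sex, coefficients = default_coefficients(),
                             noise_sd = 2.5, seed = NULL) {
  sex <- normalize_sex(sex)
  if (length(sex) == 1) sex <- rep(sex, length(ca))
  idx <- match(sex, coefficients$sex)
  if (anyNA(idx)) {
    abort_dentalage("coefficients missing for a sex", class = "dentalage_error_configuration")
  }
  with_seed(seed, {
    mu <- coefficients$a[idx] + coefficients$b[idx] * ca + coefficients$c[idx] * ca^2
    pmin(pmax(mu + rnorm(length(ca), 0, noise_sd), 0), 70)
  })
}

# Allocate `target` across 7 teeth proportionally to `weights`, capping each
# tooth at 10 and redistributing the excess over the remaining capacity.
allocate_capped <- function(target, weights) {
  v <- target * weights / sum(weights)
  for (iter in 1:10) {
    over <- v > 10
    if (!any(over)) break
    excess <- sum(v[over] - 10)
    v[over] <- 10
    room <- !over & v < 10
    if (!any(room) || excess <= 1e-12) break
    v[room] <- v[room] + excess * weights[room] / sum(weights[room])
  }
  pmin(v, 10)
}

# Snap to the Nolla lattice with error feedback: the residual of each snap is
# carried into the next tooth, keeping the snapped sum within one lattice gap
# of the raw sum.
snap_with_carry <- function(v) {
  out <- numeric(length(v))
  carry <- 0
  for (i in seq_along(v)) {
    x <- min(max(v[i] + carry, 0), 10)
    out[i] <- snap_nolla(x)
    carry <- v[i] + carry - out[i]
  }
  out
}

#' Allocate a target sum score across the seven teeth
#'
#' Distributes a target Nolla sum over teeth 31..37 proportionally to a
#' weight profile (capped at stage 10 per tooth, excess redistributed), adds
#' optional centred per-tooth jitter, and snaps each value to the Nolla
#' reading lattice with carry compensation so the snapped sum stays within
#' one lattice gap of the target when `jitter_sd = 0`.
#'
#' @param target_sum target Nolla sum in \[0, 70\].
#' @param tooth_profile 7 non-negative weights summing to 1 (default uniform).
#' @param jitter_sd SD of the centred per-tooth jitter, in stage units.
#' @inheritParams draw_ages
#' @return numeric vector of 7 Nolla stages (tooth order 31..37).
#' @export
#' @examples
#' allocate_tooth_stages(35) # each tooth at 5.0
allocate_tooth_stages <- function(target_sum, tooth_profile = rep(1 / 7, 7),
                                  jitter_sd = 0.3, seed = NULL) {
  if (length(tooth_profile) != 7 || any(tooth_profile < 0) ||
    abs(sum(tooth_profile) - 1) > 1e-9) {
    abort_dentalage(
      "tooth_profile must be 7 non-negative weights summing to 1",
      class = "dentalage_error_configuration"
    )
  }
  if (target_sum < 0 || target_sum > 70) {
    abort_dentalage("target_sum must lie in [0, 70]", class = "dentalage_error_input")
  }
  with_seed(seed, {
    v <- allocate_capped(target_sum, tooth_profile)
    if (jitter_sd > 0) {
      j <- rnorm(7, 0, jitter_sd)
      v <- pmin(pmax(v + (j - mean(j)), 0), 10)
    }
    snap_with_carry(v)
  })
}

#' Derive companion Demirjian letters from Nolla stages
#'
#' Maps each tooth's maturity fraction m = nolla/10 through fixed equal-width
#' thresholds: m = 0 gives `"0"` (no calcification), then the eight
#' right-closed bins ((k-1)/8, k/8] give letters A..H. This affine companion
#' mapping is a modelling convenience for the comparison arm; real staging
#' systems are not affine in maturity.
#'
#' @param nolla numeric vector of Nolla stages in \[0, 10\].
#' @return character vector of Demirjian stages.
#' @export
#' @examples
#' derive_demirjian_stages(c(0, 5, 10)) # "0" "D" "H"
derive_demirjian_stages <- function(nolla) {
  if (any(nolla < 0 | nolla > 10)) {
    abort_dentalage("Nolla stages must lie in [0, 10]", class = "dentalage_error_input")
  }
  m <- nolla / 10
  ifelse(m <= 0, "0", LETTERS[pmax(1L, ceiling(m * 8 - 1e-9))])
}

#' Simulate a stratified cohort
#'
#' Generates a full synthetic cohort: stratified ages per the design, latent
#' sex-specific quadratic sum scores with additive noise, per-tooth Nolla
#' stages (allocation + lattice snap), and companion Demirjian letters. The
#' latent (pre-snap) sum is retained as `nolla_sum_target` for diagnostics.
#'
#' @inheritParams draw_ages
#' @inheritParams latent_sum_score
#' @inheritParams allocate_tooth_stages
#' @param score_noise_sd SD of the additive sum-score noise (score units).
#' @param per_tooth_jitter_sd SD of the centred per-tooth jitter (stage units).
#' @return a tibble with columns `subject_id`, `sex`, `age_group`,
#'   `ca_years`, `nolla_31`..`nolla_37`, `dem_31`..`dem_37`,
#'   `nolla_sum_target`.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' nrow(cohort) # 535
simulate_cohort <- function(design = cohort_design(),
                            coefficients = default_coefficients(),
                            score_noise_sd = 2.5,
                            tooth_profile = rep(1 / 7, 7),
                            per_tooth_jitter_sd = 0.3,
                            seed = NULL) {
  validate_design(design)
  with_seed(seed, {
    ages <- draw_ages(design)
    n <- nrow(ages)
    target <- latent_sum_score(ages$ca_years, ages$sex,
      coefficients = coefficients, noise_sd = score_noise_sd
    )
    stages <- t(vapply(
      target,
      function(ts) {
        allocate_tooth_stages(ts,
          tooth_profile = tooth_profile,
          jitter_sd = per_tooth_jitter_sd
        )
      },
      numeric(7)
    ))
    colnames(stages) <- nolla_cols()
    dem <- apply(stages, 2, derive_demirjian_stages)
    colnames(dem) <- dem_cols()
    dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%04d", seq_len(n))),
      ages,
      tibble::as_tibble(stages),
      tibble::as_tibble(dem),
      tibble::tibble(nolla_sum_target = target)
    )
  })
}

#' Stratified train/test split
#'
#' Randomly partitions each design cell of a cohort into exactly
#' (`n_train`, `n_test`) subjects, adding a `dataset` column with values
#' `"train"`/`"test"`. Deterministic under a seed.
#'
#' @param cohort a cohort tibble with `sex`, `age_group` columns.
#' @inheritParams draw_ages
#' @return the cohort with a `dataset` column appended.
#' @export
split_cohort <- function(cohort, design = cohort_design(), seed = NULL) {
  validate_design(design)
  cohort <- tibble::as_tibble(cohort)
  with_seed(seed, {
    cohort$dataset <- NA_character_
    for (i in seq_len(nrow(design))) {
      cell <- which(cohort$sex == design$sex[i] & cohort$age_group == design$age_group[i])
      need <- design$n_train[i] + design$n_test[i]
      if (length(cell) < need) {
        abort_dentalage(
          sprintf(
            "cell %s/%s has %d subjects but the design needs %d",
            design$sex[i], design$age_group[i], length(cell), need
          ),
          class = "dentalage_error_partition"
        )
      }
      train_idx <- sample(cell, design$n_train[i])
      test_idx <- sample(setdiff(cell, train_idx), design$n_test[i])
      cohort$dataset[train_idx] <- "train"
      cohort$dataset[test_idx] <- "test"
    }
    cohort[!is.na(cohort$dataset), ]
  })
}

#' Re-rate stages with observer noise
#'
#' Produces a second rating of a Nolla stage vector by moving each reading to
#' an adjacent lattice value (up or down one step) with probability
#' `disagree_prob`. Used to exercise the observer-agreement (kappa)
#' machinery; this is not a model of real observer behaviour.
#'
#' @param stages numeric vector of Nolla lattice stages.
#' @param disagree_prob per-reading probability of moving one lattice step.
#' @inheritParams draw_ages
#' @return numeric vector of re-rated stages on the lattice.
#' @export
rerate_stages <- function(stages, disagree_prob = 0.05, seed = NULL) {
  lattice <- nolla_lattice()
  idx <- match(snap_nolla(stages), lattice)
  with_seed(seed, {
    move <- runif(length(idx)) < disagree_prob
    dir <- sample(c(-1L, 1L), length(idx), replace = TRUE)
    idx2 <- pmin(pmax(idx + ifelse(move, dir, 0L), 1L), length(lattice))
    lattice[idx2]
  })
}
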