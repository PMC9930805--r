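---
title: "Methods: quadratic score–age calibration for dental age estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quadratic score-age calibration for dental age estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentalage)
```

## Scope and model

`dentalage` estimates the age of children aged roughly 6–15 years from the
developmental stages of the seven left mandibular permanent teeth (FDI
31–37), as read from panoramic radiographs. The package does not read
images; its input surrogate is a per-subject table of stage assignments.

Three estimators are provided:

1. **Demirjian**: stages A–H per tooth → sex-specific self-weighted scores
   summing to a 0–100 maturity score → age via a norm table.
2. **Nolla**: stages 0–10 per tooth (fractional readings .2/.5/.7) → 0–70
   sum score → age via a norm table.
3. **Recalibrated ("new")**: the Nolla sum score $S$ is modelled per sex as
   $S = a + b\,x + c\,x^2$ in chronological age $x$, fitted by ordinary least
   squares on a training split; dental age is the analytic inverse on the
   rising branch,
   $\mathrm{DA} = \frac{-b + \sqrt{b^2 - 4c(a - S)}}{2c}$.

The quadratic family assumes tooth maturation decelerates smoothly towards a
plateau; $b > 0 > c$ over the ages of interest. With $c < 0$ the curve peaks
at the vertex $-b/(2c)$, which bounds the invertible domain from above: a
score above the curve maximum carries no age information beyond "at or past
the plateau" and is clamped to the vertex age with a flag. Estimates are
additionally clamped to the fitted age domain (the training age range), so
the estimator never extrapolates. We deliberately regress score on age and
invert — rather than regressing age on score — because the score is the
noisy measurement and age the controlled variable in a cross-sectional
calibration design; the left root is the correct branch because both
reference curves place the vertex at or above ~14.8 years.

The package's reference coefficients (`default_coefficients()`) are
male $(a,b,c) = (4.916,\ 7.783,\ -0.232)$ and female
$(-2.751,\ 9.785,\ -0.331)$, a published population-specific calibration for
children aged 6–15; they drive the synthetic generator and serve as ground
truth in recovery tests. The female vertex, $9.785/0.662 = 14.78$ y, lies
*inside* the age range — a structural feature, not an artifact: girls'
mandibular dentition is essentially complete before 15, so the score ceiling
is reached within the study window.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `score_noise_sd` | 2.5 | score units | Spread of individual sum scores around the age curve; puts the synthetic calibration $R^2$ near the low-0.9 range typical of such cohorts. A documented condition of the generator, not a fitted value. |
| `per_tooth_jitter_sd` | 0.3 | stage units | Desynchronization between teeth of one subject. Centred before use so the subject's sum is untouched and `score_noise_sd` remains the exact sum-score noise. |
| `tooth_profile` | uniform (1/7 each) | — | How the sum distributes across teeth; capped at stage 10 per tooth with excess redistributed. |
| age-group bins | nine 1-y bins over (6, 15] | years | The stratification grid of the emulated design. |
| conversion-table grid | 0.1 | years | Finer than the reporting precision (2 decimals) of ages. |
| Wilcoxon `exact_max` | 25 | n | Full exact null distribution is cheap below this; normal approximation with tie-corrected variance above. |

## The synthetic generator: what it emulates and what it does not

`simulate_cohort()` reproduces the *statistical* structure a method-comparison
study assumes: a fixed stratified design (default: 535 subjects, nine 1-year
bins per sex, cells of 18–20 training and 8–10 testing subjects, totals
358/177), ages uniform within bins (the emulated design reports only "roughly
even" coverage, and uniform is the least-informative choice matching it),
latent sum scores following the sex-specific quadratics with additive
Gaussian noise clamped to the attainable range [0, 70], allocation of each
sum across seven teeth, and snapping to the Nolla reading lattice.

It does **not** model tooth biology. In particular:

* The companion Demirjian letters are derived from the Nolla stages through
  equal-width maturity bins (`derive_demirjian_stages()`). Real staging
  systems are not affine transforms of one another; this mapping only gives
  the comparison arm structurally plausible inputs.
* The packaged score→age norms for the two classical methods are
  **synthetic** (`*_synthetic.csv`, built by `data-raw/build_lookup_tables.R`).
  The Nolla norms are the generating quadratic shifted +0.40 y, so the
  classical Nolla lookup underestimates CA by about 0.4 y on generated
  cohorts; the Demirjian norms are the generator's induced mean maturity
  trajectory shifted −0.24 y, producing a comparable overestimate. These
  shifts emulate the direction and size of population-mismatch biases
  reported for the classical methods; they are *not* the historical norm
  tables, and results obtained through them say nothing about the historical
  methods on real radiographs. The per-tooth Demirjian stage scores, by
  contrast, are the classical seven-tooth tables (each sex's stage-H row sums
  to exactly 100, asserted at load).
* Passing tests therefore demonstrate internal consistency of the pipeline
  and correct arithmetic of every step — not accuracy of any method on real
  children.

## Numerical and procedural choices

* **Decimal ages.** Chronological age is the day count divided by 365.25;
  rounding happens only at presentation.
* **Age-group binning.** Ages are rounded *half-up* at two decimals before
  binning into (x.00, (x+1).00], so 7.00 belongs to "6.01–7.00" and 7.005 to
  "7.01–8.00". Base `round()` (round-half-even on binary doubles) would send
  7.005 down; a scale-relative epsilon enforces the decimal convention.
* **Lattice snapping.** Per-tooth values are snapped to the Nolla lattice
  with carry compensation (each snap's residual feeds the next tooth), so
  the snapped sum stays within one lattice gap (≤ 0.15) of the target. The
  unsnapped latent sum is kept as `nolla_sum_target` for diagnostics. The
  snap residual is a deterministic sawtooth in age, which leaves a small
  (≲ 0.05) bias on the fitted linear coefficient in noiseless runs; the
  unsnapped control recovers the coefficients exactly.
* **Inversion conditioning.** At the vertex the curve is flat, so score→age
  is ill-conditioned there: a relative score perturbation of $10^{-14}$
  already moves the root by $\sim 10^{-7}$ y. Round-trip accuracy of
  $10^{-9}$ y is therefore asserted on grids that stop $10^{-3}$ y short of
  the vertex; at the vertex itself only the clamping contract is tested.
* **Normality gate.** The Kolmogorov–Smirnov test is run against a normal
  with mean and SD estimated from the sample (asymptotic p). Estimated
  parameters make the test conservative (the Lilliefors caveat); this is
  documented as an approximation matching common applied practice. Samples
  with n < 4 or zero variance skip the gate and are treated as non-normal.
* **Wilcoxon policy.** Zeros dropped, mid-ranks for ties, exact two-sided p
  ($2\min(P(W^+\le w), P(W^+\ge w))$, capped at 1) from the full null
  distribution computed by convolution on doubled ranks — valid under ties —
  for n ≤ 25; tie-corrected normal approximation (no continuity correction)
  above. All-zero samples return p = 1 by convention, flagged.
* **Kappa pooling.** Observer agreement pools all (subject, tooth)
  assignments into one rating sequence per rater (e.g. 50 radiographs × 7
  teeth = 350 items), unweighted. Identical constant raters make
  $p_e = 1$ and κ undefined (returned as `NA` with a warning).
* **Degenerate fits.** Fewer than 3 distinct ages is a rank-deficiency
  error; zero score variance or an essentially zero quadratic coefficient
  flags the model degenerate, and inversion refuses such models.
* **CI of MD** uses the t quantile, $\mathrm{MD} \pm t_{0.975,\,n-1}\,
  \mathrm{SD}/\sqrt{n}$.

## Known limitations

* **Inverse-prediction variance grows with age.** The calibration flattens
  towards the vertex, so a fixed score noise maps to an age error that grows
  from ~0.5 y at age 8 to well over 1 y past age 13. Group-level MAD is
  therefore age-dependent by construction.
* **Score ceiling censoring.** Sum scores cannot exceed 70, and near-mature
  subjects pile up at the ceiling. This right-censoring pulls the fitted
  quadratic's vertex below the true one, which caps top-bin estimates and
  induces a small negative bias there. Consequently the grand-total MD of a
  calibrate-on-train/evaluate-on-test run fluctuates at the several-hundredths
  scale between replicates (train-sampling moves the whole fitted curve);
  `scripts/acceptance.R` reports the 20-seed |MD| ≤ 0.1 y pass rate so this
  stability is measured, not assumed.
* **Norms are stand-ins.** See above; classical-method results on synthetic
  cohorts characterize the pipeline, not the historical methods.
* Third molars, maxillary teeth, and image-based staging are out of scope.

## Problem sizes

The test suite and acceptance script use the default design (535 subjects)
throughout: single runs for report-shape and identity checks, 5-seed panels
for snapping-bias properties, 20-seed sweeps for end-to-end MD stability,
100 replicates for coefficient-recovery-under-noise, and $10^4$-point grids
per sex for inversion round-trips — sizes chosen to make the Monte-Carlo
assertions stable at their stated tolerances.
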