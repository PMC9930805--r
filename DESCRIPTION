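Package: dentalage
Title: Dental Age Estimation from Tooth Developmental Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dental age estimation in children from developmental
    stages of the seven left mandibular permanent teeth (FDI 31-37). Implements
    Demirjian maturity scoring and Nolla sum scoring with score-to-age
    conversion, a sex-specific quadratic calibration of Nolla sum score on
    chronological age with analytic inversion into dental-age conversion
    tables, and the standard accuracy-evaluation protocol for age-estimation
    methods (mean difference, mean absolute difference, normality-gated paired
    tests, Cohen's kappa for observer agreement). Includes a synthetic-cohort
    generator emulating an age- and sex-stratified radiographic study design
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
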