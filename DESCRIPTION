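Package: accelcohort
Title: Accelerometer Data Reduction and Cohort Activity Summaries for
    Child Physical Activity Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces epoch-level accelerometer count/step recordings from
    child cohort studies to per-child physical-activity summaries and
    survey-weighted cohort statistics. Implements spurious-count removal,
    non-wear bout detection (consecutive-zero rule), wear-period start/end
    detection, valid-day and valid-child selection, counts-per-minute
    cut-point intensity classification, standard-day wear-time
    standardization, physical-activity guideline adherence, cut-point
    sensitivity analysis, season-standardized weighted quantiles,
    marginally standardized adjusted prevalences from weighted logistic
    models, Benjamini-Hochberg multiple-comparison annotation, and Moran's
    I spatial autocorrelation over region graphs. A seeded synthetic
    cohort generator with full latent ground truth makes every pipeline
    stage testable without access to restricted cohort data.
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
    purrr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
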