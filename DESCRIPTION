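Package: growthsel
Title: Out-of-Sample Selection Among Non-Nested Longitudinal Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares non-nested models for sparse longitudinal child growth
    data by out-of-sample predictive accuracy. Provides three model families
    (a truncated cubic spline linear mixed effects model with continuous-AR(1)
    within-subject errors, sparse functional principal component analysis, and
    functional concurrent regression with a time-invariant sex effect), four
    subject-specific error metrics (MSE, normalized MSE, age-stratified MSE,
    and growth-velocity-weighted MSE), four hold-out scenarios (backward,
    forward, in-range, and new-individual prediction), and a synthetic cohort
    generator with known ground truth so the full comparison runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mgcv,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
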