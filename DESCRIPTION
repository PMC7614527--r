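Package: statedyn
Title: Temporal Dynamics of Brain-Network States from fMRI Component Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits shared-covariance multivariate Gaussian hidden Markov models to
    per-subject fMRI component time courses and derives temporal-dynamics metrics
    (fractional occupancy, switching rate, transition and persistence probabilities).
    Provides compositional principal component analysis of state occupancies with
    broken-stick component selection and varimax rotation, cross-sectional group
    inference with mixed-effects models and max-statistic permutation testing with
    nuisance covariates, and a two-step mixed-effects prediction of longitudinal
    cognitive decline from baseline network dynamics. Includes a synthetic-cohort
    generator with planted group effects so every pipeline stage can be validated
    without access to scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    lme4,
    lmerTest,
    clue,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
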