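Package: dietme
Title: Measurement Error Models for Dietary Validation Studies with a
    Surrogate Biomarker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits an extended longitudinal measurement error model for
    self-reported dietary intake measured by a food frequency
    questionnaire and a food record together with a surrogate
    (concentration) biomarker, repeated over time.  Measurements are
    related to a latent long-term intake with time-specific
    within-person deviations; errors in the self-reported instruments
    may be correlated with each other and across repeats.  Fitting is
    by full-cohort maximum likelihood under multivariate normality
    with arbitrary missingness patterns (valid under missing at
    random), with a two-step residual adjustment for covariates and
    mixed-model estimation of covariate effects.  Regression dilution
    ratios and correlations with true intake are derived in closed
    form with delta-method or bootstrap standard errors.  The scaling
    bias of the food record and the correlation between repeated
    biomarker errors are not identified by the data; the package
    drives sensitivity analyses over a grid of fixed values for the
    pair.  A synthetic-data generator reproducing the model's full
    stochastic structure (correlated errors, covariates, MCAR/MAR
    missingness, zero intakes, biomarker outliers) is included, along
    with CSV input, preprocessing filters and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
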