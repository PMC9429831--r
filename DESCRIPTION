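Package: apcmort
Title: Age-Period-Cohort Decomposition of Mortality Surfaces with the
    Intrinsic Estimator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for age-period-cohort (APC) analysis of mortality
    surfaces tabulated by single year of age and calendar year. Builds the
    deviation-coded APC design matrix, characterises its one-dimensional
    null space, and fits the rank-deficient Poisson log-rate model by the
    Intrinsic Estimator (principal-components route), with a constrained
    fit as an estimable-function oracle. Derives crude, directly
    age-standardized, and age-cohort adjusted rate series from a fitted
    model; interpolates sparse prevalence series to annual resolution; and
    correlates adjusted rates with obesity prevalence and cohort effects
    with historical smoking prevalence. Includes a synthetic Lexis-surface
    generator (Poisson death counts over curvilinear age, piecewise-linear
    period, and declining cohort effects) so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
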