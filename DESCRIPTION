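Package: stancova
Title: Standardized Contrasts in ANCOVA: Exact Confidence Intervals,
    Precision Assessment, and Sample Size Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interval estimation for standardized linear contrasts of
    adjusted group means in the analysis of covariance (ANCOVA) with one
    or more covariates.  Implements the exact confidence interval based on
    inverting the noncentral t distribution, together with the asymptotic
    (normal-approximation) and direct-division intervals, for raw data or
    summary statistics.  Under the unconditional model with stochastic
    multinormal covariates, the exact expected width and assurance
    probability of the exact interval are computed by nested quadrature
    over a noncentral F covariate factor and a noncentral t statistic, and
    minimal sample sizes meeting an expected-width or assurance-probability
    criterion are determined.  Monte Carlo engines reproduce the coverage
    and precision behaviour of the three interval procedures, including
    non-normal error and covariate variants, and double as synthetic-data
    generators.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
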