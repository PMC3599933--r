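Package: lagmeta
Title: Two-Stage Analysis of Distributed Lag Non-Linear Models
Version: 0.1.0
Authors@R: person("lagmeta", "authors", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Tools for two-stage multi-location time-series analysis with
    distributed lag non-linear models (DLNMs). Builds cross-basis design
    matrices from tensor products of predictor- and lag-space bases, fits
    location-specific quasi-Poisson regressions, reduces the bi-dimensional
    fitted surface to one-dimensional summaries (overall cumulative,
    predictor-specific and lag-specific) through rank-deficient linear maps
    applied to coefficients and their covariance, and pools the reduced
    coefficients across locations with multivariate random-effects
    meta-analysis and meta-regression estimated by (restricted) maximum
    likelihood, including multivariate Cochran Q, I-squared and Wald tests.
    A synthetic multi-region data generator with a known exposure-lag-response
    surface supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
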