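Package: vfvar
Title: Heteroscedastic Variability and Pointwise Trend Models for Longitudinal Visual Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify measurement variability in longitudinal
    standard automated perimetry and to compare pointwise trend models of
    threshold sensitivity over time. Provides the 24-2 test grid with
    eccentricity bands and reliability filters; unweighted, variance-weighted,
    exponential (decay and improvement) and logistic pointwise regressions
    with floor and ceiling censoring; estimation of residual standard
    deviation as a function of threshold sensitivity with log-linear and
    piecewise-linear (spline) summaries; a synthetic-cohort generator with
    sensitivity-dependent Gaussian noise for simulation studies; and a
    rolling-origin prediction benchmark comparing models by root-mean-square
    error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
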