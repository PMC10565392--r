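Package: treedemog
Title: Hierarchical Bayesian Models of Tree Growth and Mortality Along
    Soil Resource Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level hierarchical Bayesian analysis of tree growth and
    mortality in forest census-plot networks spanning soil phosphorus and
    moisture gradients. Growth is modelled with a robust Student-t
    likelihood with an estimated normality (degrees-of-freedom) parameter;
    mortality with an interval-censored Bernoulli model in which annual
    survival is raised to the power of the census interval. Species-level
    coefficients are regressed, at a second level, on species associations
    with soil phosphorus, shade and moisture. Includes a distance-weighted
    shading (neighbourhood crowding) index with AIC selection of per-size-
    class distance-decay coefficients, a synthetic census generator for
    parameter-recovery testing, standardized demographic predictions along
    the phosphorus gradient, and abundance-weighted growth-mortality
    trade-off regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
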