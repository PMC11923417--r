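Package: equivcurve
Title: Model-Averaged Equivalence Testing for Dose-Response and
    Time-Response Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether two groups' regression curves (dose-response or
    time-response) are equivalent, i.e. whether the maximal absolute
    deviation between the fitted curves stays below a pre-specified
    margin.  Curves are estimated by model averaging over a set of
    candidate nonlinear regression families (linear, quadratic, emax,
    exponential, sigmoid emax, beta) with smooth Bayesian information
    criterion weights, which makes the test robust to model
    misspecification.  The decision uses the duality between confidence
    intervals and hypothesis tests: equivalence is concluded when the
    margin exceeds a one-sided upper confidence bound for the maximal
    deviation, obtained from a parametric bootstrap (percentile or hybrid
    normal-approximation bound).  Includes a simulation framework for
    type-I-error and power studies, a per-gene screening mode for
    time-course expression data with range-scaled margins, synthetic data
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
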