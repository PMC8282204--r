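Package: growthmc
Title: Monte Carlo Evaluation of Three-Level Linear Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulation studies of sample-size adequacy in
    three-level linear growth models, where repeated measures are nested
    in individuals and individuals are nested in groups.  Provides a
    hierarchical data generator driven by intraclass-correlation
    specifications, a profiled maximum-likelihood estimator for the
    three-level random-intercept/random-slope model with Wald inference
    and admissibility classification, Monte Carlo outcome statistics
    (convergence rate, relative bias, mean squared error, confidence
    interval coverage, power), and a replication harness that runs full
    condition grids and writes publication-shaped summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
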