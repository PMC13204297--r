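Package: screentrend
Title: Bayesian Logit-Linear Trend Projection of Cancer Screening Coverage
Version: 1.0.0
Authors@R:
    person("Screening", "Trends Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits per-unit Bayesian linear trend models to triennial survey
    estimates of cancer screening coverage on the logit scale, projects
    coverage forward by Markov chain Monte Carlo, and derives the indicators
    used to monitor attainment of a national coverage benchmark: posterior
    exceedance probabilities at a policy horizon, the first calendar year at
    which attainment becomes probable, annual percentage-point change with
    credible intervals, and male-female disparity metrics. Includes a holdout
    forecast-validation protocol, a synthetic survey-panel generator with
    known ground truth for calibration experiments, packaged reference tables
    of prefecture-level screening coverage, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
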