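Package: sevocea
Title: Bayesian Cost-Effectiveness Analysis of Topical Sevoflurane for
    Painful Leg Ulcers
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for Bayesian cost-effectiveness analysis
    of domiciliary topical sevoflurane added to conventional analgesia for
    painful, nonrevascularizable leg ulcers.  Computes the SPID (Sum of
    Pain Intensity Difference) effectiveness statistic with
    last-observation-carried-forward, annual per-patient costing in
    reference-year euros with DRG-based hospitalization variants, a
    bivariate Gibbs sampler for the joint regression of log annual cost
    and SPID on baseline covariates, cost-ratio / dominance / acceptability
    curve summaries, a scenario sensitivity suite, and a synthetic cohort
    generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
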