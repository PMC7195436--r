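Package: czdown
Title: Critical Slowing Down Biomarkers and Phase-Based Seizure Forecasting
Version: 0.1.0
Authors@R:
    person("czdown", "maintainers", email = "maintainers@czdown.org",
           role = c("aut", "cre"))
Description: Tools to quantify critical slowing down in long-term
    intracranial EEG sampled as short periodic snapshots, and to turn the
    resulting biomarkers into phase-conditioned seizure-risk forecasts.
    Implements autocorrelation half-width, segment variance and
    template-based epileptiform spike rates; causal moving-average
    decomposition into circadian and multidien rhythms with Hilbert
    phases; phase synchronization indices; within-sample (M1) and
    pseudoprospective (M2) three-state risk forecasters benchmarked
    against a random Markov predictor; inter-seizure-interval cluster
    analysis; and a seeded synthetic-recording generator built on a
    driven bistable stochastic model so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
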