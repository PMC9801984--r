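Package: declinesim
Title: Simulation-Based Evaluation of Genomic Methods for Detecting Recent
    Population Declines
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-time, individual-based simulation of pedigrees under
    annual or overlapping-generation life histories, pedigree-conditioned
    transmission of chromosome segments, and coalescent completion of founder
    ancestry, yielding genotypes sampled at up to five time points (0 to 120
    years before present).  Includes dataset builders for temporal sampling
    schemes and whole-genome or RAD-like data, a composite-likelihood folded
    site-frequency-spectrum fitter with AIC model selection, two linkage-
    disequilibrium effective-population-size estimators (an unlinked-pair
    single-sample estimator with jackknife confidence intervals and a
    recombination-binned trajectory estimator with SNP-resampling confidence
    intervals), and the evaluation statistics (power, mean absolute
    percentage error, log-ratio bias) needed to benchmark decline-detection
    study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
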