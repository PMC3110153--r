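Package: estrogram
Title: Quantitative-Phenotype Gene Expression Association via Bayesian
    Variable Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Associates a quantitative behavioral phenotype (the average
    heat score of dairy cows) with per-gene brain expression measured as
    two-color microarray M-values. Builds an orthonormal polynomial basis
    of the phenotype, fits a per-gene Bayesian hierarchical model with
    spike-and-slab coefficient selection by Gibbs sampling, calls
    significant probes by multi-chain consensus with a Bayesian false
    discovery rate estimate, classifies linear and quadratic association
    patterns, and tests gene sets for over-representation with Fisher's
    exact test and the EASE score. A synthetic-data generator with known
    planted associations provides ground truth for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
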