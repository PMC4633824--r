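Package: eqtel
Title: Coupled Bayesian Regression for Causal Regulatory eQTL Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects putatively causal regulatory SNPs underlying gene
    expression variance by coupling two Bayesian regression models: a
    per-gene spike-and-slab variable-selection regression with a Zellner
    g-prior and epigenetically informed inclusion priors, and a shared
    Bayesian logistic regression (Polya-Gamma augmented) that estimates each
    SNP-gene pair's regulatory-interaction potential from epigenetic and
    interaction features. Inference runs a hierarchical Markov chain Monte
    Carlo that explores LD blocks at the top level and sparse SNP sets
    within blocks, reporting Rao-Blackwellized posterior inclusion
    probabilities. Includes a semi-synthetic benchmark generator with known
    causal ground truth, precision-recall and cross-validated
    predictability evaluation, and downstream functional-validation
    statistics (exact PWM match P values, motif-disruption enrichment,
    footprint overlap, allelic imbalance, causal-fraction estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Biostrings,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
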