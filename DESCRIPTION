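Package: lnmsig
Title: Lymph-Node Metastasis Signature Discovery for Multisite Proteomics
Version: 0.1.0
Authors@R:
    person("LNM", "Signatures Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for label-free quantitative
    proteomics of multisite tumor cohorts: down-shifted-normal imputation of
    left-censored (MNAR) missing values, two-group differential abundance
    with detection-exclusivity rules and Benjamini-Hochberg correction,
    hierarchical clustering over a linkage-method by distance-metric grid
    with Fisher-exact covariate association, epithelial-mesenchymal
    transition (EMT) scoring of paired tumor/lymph-node proteomes,
    targeted-assay (SRM/PRM and RT-qPCR) quantification and quality-control
    arithmetic, and an exhaustive signature-by-classifier machine-learning
    search with repeated stratified cross-validation, equivalence selection
    against the top-ranked pair and permutation validation. Includes a
    synthetic-data generator with planted ground truth for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    vegan,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
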