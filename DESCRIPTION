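Package: efoscreen
Title: Enrichment Factor Optimization for Consensus Virtual Screening
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds consensus scoring models for structure-based virtual
    screening by linearly combining docking and rescoring scores. Candidate
    score subsets of one to three functions are enumerated exhaustively after
    variance-inflation-factor and single-score enrichment prefiltering, and
    the combination coefficients are fitted by a derivative-free random-restart
    pattern search that maximizes a cluster-based enrichment quality function.
    Models are screened by repeated stratified train/test validation and
    assessed with enrichment factors at fixed ranking fractions and ROC AUC.
    Includes a generator of DUD-like active/decoy benchmark tables with a
    planted linear signal for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Cheminformatics, StructuralPrediction, Classification
RoxygenNote: 7.3.3
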