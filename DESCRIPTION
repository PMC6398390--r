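Package: rulereject
Title: Sparse Interval-Rule Ensembles with a Reject Option for Clinical Triage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits sparse, interpretable classifiers whose decision function
    is a weighted sum of short conjunction rules over feature intervals,
    trained by L1-regularised linear programming with column generation and
    a branch-and-bound weighted itemset miner as the pricing oracle. A
    double-hinge surrogate loss embeds a rejection (abstain) option;
    isotonic calibration maps scores to posterior probabilities, and a
    minimum-expected-cost rule classifies, rejects, or refers each subject.
    Includes a two-stage screening cost model for clinical triage, a
    synthetic biomarker-panel generator with planted rules for validation,
    an intersection-matrix visualisation of fitted rule sets, and a
    repeated stratified cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
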