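Package: pep1433
Title: Affinity-Based Prediction of 14-3-3 Phosphopeptide Binding Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts binding affinities of hexapeptide phosphomotifs
    (P-3 P-2 P-1 - pS/T - P+1 P+2 P+3) to the seven human 14-3-3 isoforms.
    Enumerates fragment-based combinatorial sublibraries, selects relevant
    training motifs by amino-acid category overlap, encodes each motif with
    27 position-wise physicochemical descriptors plus 27 auto-cross
    covariance terms, and fits a per-query elastic-net regression with
    cross-validated penalty selection.  Includes evaluation metrics,
    position-weight-matrix and isoform-specificity analyses, a similarity
    score with a randomization test, a synthetic affinity generator for
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
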