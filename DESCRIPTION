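Package: viroSGT
Title: Host-Domain Classification of Virus Sequence Fragments via
    Trinucleotide Graph Transforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Distinguishes prokaryotic-virus (phage) from eukaryotic-virus
    DNA fragments directly from sequence composition. Each fragment is
    encoded as a 64 x 64 pattern matrix summarising, for every ordered pair
    of overlapping trinucleotides, the exponentially decayed distances
    between their occurrences (a sequence graph transform), and classified
    by a self-contained two-layer 2D convolutional network trained with
    Adam on categorical cross-entropy. Includes a Markov-chain virome
    fragment simulator with length groups, sequencing-error injection and
    leakage-free genome-level fold splits; a windowed FASTA inference
    pipeline with length-weighted score aggregation and an optional
    nonviral filter; and an evaluation harness (sensitivity, specificity,
    accuracy, precision, F1, ROC-AUC, average precision, k-fold
    cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
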