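Package: protfun
Title: Protein Function Prediction with Dilated Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein function labels (EC-style and GO-style
    vocabularies) directly from unaligned amino-acid sequences using a
    dilated residual convolutional network with mean pooling and a
    multi-label sigmoid head. Includes ontology handling with ancestor
    closure of leaf annotations, corpus construction with random and
    cluster-aware train/dev/test splits, a seeded synthetic-proteome
    generator with planted motifs for benchmarking, micro-averaged
    precision/recall and Fmax evaluation with bootstrap confidence
    intervals, a Smith-Waterman nearest-neighbour label-transfer baseline
    with bit-score confidence and a bit-score-times-probability ensemble,
    and class-activation mapping for coarse functional localisation and
    domain ordering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    yaml
Config/testthat/edition: 3
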