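Package: dbpWET
Title: DNA-Binding Protein Prediction from Word-Embedding Encodings of
    Protein Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts DNA-binding proteins from primary sequence alone.
    Protein sequences are tokenised into overlapping k-mer "words" and
    encoded with three unsupervised word-embedding schemes (continuous
    bag-of-words, GloVe and a subword/fastText-style encoder). The three
    per-sequence feature blocks are fused by weighted concatenation, with
    block weights learned by differential evolution against a
    cross-validated ridge-classifier objective. Features are then ranked
    by Shapley-value importance (exact enumeration, permutation sampling,
    and a gradient-boosted-tree surrogate for wide matrices) and top-k
    subsets are evaluated with a one-dimensional convolutional network
    under stratified cross-validation. Includes a synthetic planted-motif
    sequence generator so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    Biostrings,
    S4Vectors,
    xgboost,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Classification, Proteomics, MachineLearning, FeatureExtraction
RoxygenNote: 7.3.3
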