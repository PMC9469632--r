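Package: cmic
Title: Classifying DNA Methylation Inheritance of CpG Islands from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a CpG island (CGI) methylated in fully grown
    oocytes retains its DNA methylation in the maternal genome of the
    blastocyst, from sequence alone. A CGI sequence is augmented into many
    variable-length k-mer sentences (non-overlapping random splits of the
    sequence and its reverse complement), k-mer embedding vectors are learned
    with a CBOW word2vec model over those sentences (splitDNA2vec), and a
    bidirectional gated recurrent unit (BiGRU) network classifies each
    sentence, aggregating cognate predictions per CGI. Includes WGBS-based
    methylation labeling (M2M/M2U inheritance classes), a stratified
    cross-validation harness with balanced accuracy, F-measure, MCC and AUC,
    experiment drivers (k-range, augmentation-count and embedding-scheme
    sweeps, long-CGI generalization), and a synthetic CGI generator with
    planted motifs for fully reproducible testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
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
    jsonlite,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
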