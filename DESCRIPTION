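Package: methylGlove
Title: DNA Methylation Site Prediction from k-mer GloVe Embeddings with a
    Dilated-Convolution Transformer Classifier
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts 5mC DNA methylation sites from fixed-length sequence
    fragments (41 bp, candidate cytosine at the center). Fragments are
    tokenized into overlapping 3-mers, embedded with GloVe word vectors
    fitted to a global k-mer co-occurrence matrix, and classified with a
    neural network combining three parallel dilated 1D convolutions, a
    Transformer encoder with sinusoidal positional encoding and multi-head
    self-attention, and a dense head with dropout. Includes confusion-matrix
    metrics (sensitivity, specificity, accuracy, Matthews correlation) and
    ROC/AUC, a synthetic planted-motif fragment generator with configurable
    class imbalance for end-to-end testing, and a pipeline runner with a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
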