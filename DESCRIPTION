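Package: phosppi
Title: Phosphorylation Site and Protein-Protein Interaction Effect
    Prediction from Sequence Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies functional phosphorylation sites on serine,
    threonine and tyrosine residues from per-residue protein language
    model embeddings, and classifies whether phosphorylation at a site
    enhances or inhibits a specific protein-protein interaction. The
    site classifier couples a convolutional encoder with an attention
    decoder; the interaction-effect classifier is a soft-voting ensemble
    of an attention-gated convolutional network and a cross-attention
    transformer over local site windows and global embeddings of both
    partners. Includes a deterministic mock embedding backend, a
    synthetic data generator with a plantable sequence signal, training
    with rectified Adam and Lookahead, and the standard evaluation
    metrics for imbalanced binary classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
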