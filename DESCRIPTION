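Package: convdti
Title: Drug-Target Interaction Prediction with Protein Sequence Convolutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTIs) from raw protein
    sequences and Morgan/circular drug fingerprints with a convolutional
    neural network: trainable amino-acid embeddings, multi-window-size 1D
    convolutions with masked global max-pooling, and fully connected layers
    joining protein and drug features under a sigmoid output. Includes
    AUPR-driven grid search, equal-error-rate threshold selection,
    confusion-matrix/ROC/PR evaluation with novelty splits, a Monte-Carlo
    binding-site attribution statistic with Benjamini-Hochberg adjustment,
    and a synthetic motif-implantation data generator so the full pipeline
    is exercisable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
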