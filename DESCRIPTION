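Package: medtext
Title: Hybrid Convolutional-Recurrent Classifiers for Medical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for document-level classification of medical and biomedical
    text with two hybrid deep-learning architectures implemented from first
    principles: a quad-channel model that runs parallel convolutional and LSTM
    branches over both word-level and character-level embeddings with a hybrid
    (additive) attention layer, and a parallel CNN / stacked-BiGRU model with
    multihead scaled-dot-product self-attention. Includes corpus input/output
    and deterministic splitting, word- and character-level tokenization and
    vocabulary building, skip-gram (word2vec) embedding training with negative
    sampling, seeded training with Adam/Nadam/SGD/AdaGrad optimizers,
    confusion-matrix metrics, a hyperparameter sweep engine, and a synthetic
    labeled-corpus generator with controllable word- and character-level class
    signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
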