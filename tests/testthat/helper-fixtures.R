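# Shared small fixtures, generated in code at test time.

tiny_corpus <- function() {
  as_labeled_corpus(data.frame(
    text = c("tumor growth factor", "cell cycle arrest",
             "invasion and metastasis", "glucose metabolism shift"),
    label = c("a", "b", "a", "b")
  ))
}

# Reduced-configuration study conditions used by the learning-sanity and
# ablation checks: 2000 documents, 2 classes, noiseless, short documents.
reduced_corpus <- function(seed, keyword_rate = 0.15, char_rate = 0.5) {
  generate_corpus(synth_spec(n_docs = 2000, n_classes = 2,
                             doc_len = c(20, 40), bg_vocab = 500,
                             keywords_per_class = 8,
                             keyword_rate = keyword_rate,
                             char_rate = char_rate,
                             label_noise = 0, seed = seed))
}

# Encode a corpus split with n_w = n_c = 64 at the reduced model size.
reduced_data <- function(corpus, with_char = TRUE, split_seed = 1) {
  spl <- split_corpus(corpus, seed = split_seed)
  wv <- build_vocab(spl$train, "word", min_count = 2)
  cv <- if (with_char) build_vocab(spl$train, "char") else NULL
  enc <- function(x) encode_corpus(x, wv, 64, cv, if (with_char) 64 else NULL)
  list(train = enc(spl$train), val = enc(spl$val), test = enc(spl$test),
       word_vocab = wv, char_vocab = cv)
}

reduced_qc <- function(data, seed, channels = c("word", "char")) {
  emb <- random_embedding(data$word_vocab, 16, seed = derive_fixture_seed(seed, 1))
  cemb <- if ("char" %in% channels)
    random_embedding(data$char_vocab, 16, seed = derive_fixture_seed(seed, 2)) else NULL
  build_qc_lstm(emb, cemb, n_classes = 2, n_w = 64,
                n_c = if ("char" %in% channels) 64 else NULL,
                widths = c(1, 3, 5), n_filters = 16, hidden = 16,
                dropout = 0.5, activation = "relu", channels = channels,
                seed = seed)
}

reduced_bigru <- function(data, seed) {
  emb <- random_embedding(data$word_vocab, 16, seed = derive_fixture_seed(seed, 1))
  build_bigru_mha(emb, n_classes = 2, n_w = 64, widths = c(1, 3, 5),
                  n_filters = 16, hidden = 16, layers = 2, n_heads = 8,
                  dropout = 0.4, activation = "sigmoid", seed = seed)
}

reduced_config <- function(seed) {
  train_config(batch_size = 32, optimizer = "adam", lr = 0.01,
               epochs = 10, patience = 5, seed = seed)
}

derive_fixture_seed <- function(seed, k) as.integer(seed * 131 + k)
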