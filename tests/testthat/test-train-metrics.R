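test_that("confusion counts match hand counts and a brute-force tally", {
  cc <- confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1), 2)
  pos <- cc[cc$class == 1, ]
  expect_equal(c(pos$tp, pos$tn, pos$fp, pos$fn), c(2, 1, 1, 1))
  same <- confusion_counts(c(0, 1, 2), c(0, 1, 2), 3)
  expect_true(all(same$fp == 0) && all(same$fn == 0))

  withr::with_seed(5, {
    pred <- sample(0:2, 200, replace = TRUE)
    truth <- sample(0:2, 200, replace = TRUE)
    cc <- confusion_counts(pred, truth, 3)
    for (k in 0:2) {
      tp <- 0; fp <- 0; fn <- 0; tn <- 0
      for (i in seq_along(pred)) {
        if (pred[i] == k && truth[i] == k) tp <- tp + 1
        else if (pred[i] == k) fp <- fp + 1
        else if (truth[i] == k) fn <- fn + 1
        else tn <- tn + 1
      }
      row <- cc[cc$class == k, ]
      expect_equal(c(row$tp, row$tn, row$fp, row$fn), c(tp, tn, fp, fn))
      expect_equal(row$tp + row$tn + row$fp + row$fn, 200)
    }
  })
  expect_error(confusion_counts(c(0, 1), c(0, 1, 1), 2),
               class = "medtext_validation_error")
})

test_that("metrics follow the binary formulas and the published F1 arithmetic", {
  # TP=3 TN=4 FP=1 FN=2 (class 1 positive)
  pred <- c(rep(1, 3), rep(0, 4), rep(1, 1), rep(0, 2))
  truth <- c(rep(1, 3), rep(0, 4), rep(0, 1), rep(1, 2))
  m <- metrics_from_counts(confusion_counts(pred, truth, 2))
  expect_equal(m$accuracy, 70)
  expect_equal(m$precision, 75)
  expect_equal(m$recall, 60)
  expect_equal(m$f1, 66.67)
  # published (precision, recall) pairs reproduce the printed F1
  expect_equal(round(f1_score(71.95, 70.67), 2), 71.30)
  expect_equal(round(f1_score(88.38, 84.15), 2), 86.21)
  expect_equal(f1_score(0, 0), 0)
})

test_that("prediction uses argmax with ties to the lowest class", {
  s_corp <- generate_corpus(synth_spec(n_docs = 20, doc_len = c(4, 8), seed = 2))
  wv <- build_vocab(s_corp, "word")
  b <- encode_corpus(s_corp, wv, 8)
  emb <- random_embedding(wv, 5, seed = 1)
  m <- build_bigru_mha(emb, n_classes = 3, n_w = 8, widths = c(1, 2),
                       n_filters = 2, hidden = 2, layers = 1, n_heads = 1,
                       seed = 3)
  m$params$dense$W[] <- 0; m$params$dense$b[] <- 0  # uniform probabilities
  expect_true(all(predict_labels(m, b) == 0L))
  m$params$dense$b <- c(0, 1, 0)
  expect_true(all(predict_labels(m, b) == 1L))
  # invariant to batch ordering
  perm <- sample(20)
  expect_equal(predict_labels(m, medtext:::subset_batch(b, perm)),
               predict_labels(m, b)[perm])
})

test_that("a perfect and a majority-class predictor get the expected metrics", {
  truth <- rep(c(0L, 1L), each = 25)
  perfect <- metrics_from_counts(confusion_counts(truth, truth, 2))
  expect_equal(unlist(perfect[, c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 100, precision = 100, recall = 100, f1 = 100))
  suppressWarnings(
    majority <- metrics_from_counts(confusion_counts(rep(0L, 50), truth, 2)))
  expect_equal(majority$accuracy, 50)
})

test_that("training is seed-deterministic and a zero learning rate is a no-op", {
  corp <- generate_corpus(synth_spec(n_docs = 60, doc_len = c(5, 10), seed = 7))
  spl <- split_corpus(corp, seed = 1)
  wv <- build_vocab(spl$train, "word")
  tr <- encode_corpus(spl$train, wv, 10)
  va <- encode_corpus(spl$val, wv, 10)
  emb <- random_embedding(wv, 5, seed = 1)
  mk <- function() build_bigru_mha(emb, n_classes = 2, n_w = 10, widths = c(1, 2),
                                   n_filters = 2, hidden = 3, layers = 1,
                                   n_heads = 2, dropout = 0.3, seed = 4)
  cfg <- train_config(batch_size = 16, lr = 0.01, epochs = 2, seed = 11)
  h1 <- train_model(mk(), tr, va, cfg)$history
  h2 <- train_model(mk(), tr, va, cfg)$history
  expect_identical(h1, h2)

  cfg0 <- train_config(batch_size = 16, lr = 0, epochs = 1, seed = 11)
  m <- mk()
  trained <- train_model(m, tr, val_batch = NULL, cfg0)
  expect_identical(trained$params, m$params)
})

test_that("optimizer variants all reduce the training loss", {
  corp <- generate_corpus(synth_spec(n_docs = 120, doc_len = c(5, 10),
                                     keyword_rate = 0.3, seed = 13))
  spl <- split_corpus(corp, seed = 1)
  wv <- build_vocab(spl$train, "word")
  tr <- encode_corpus(spl$train, wv, 10)
  emb <- random_embedding(wv, 6, seed = 1)
  for (optname in c("adam", "sgd", "nadam", "adagrad")) {
    m <- build_bigru_mha(emb, n_classes = 2, n_w = 10, widths = c(1, 2),
                         n_filters = 2, hidden = 3, layers = 1, n_heads = 2,
                         dropout = 0, seed = 4)
    lr <- if (optname %in% c("sgd", "adagrad")) 0.1 else 0.01
    h <- train_model(m, tr, NULL,
                     train_config(batch_size = 32, optimizer = optname,
                                  lr = lr, epochs = 3, seed = 1))$history
    expect_lt(h$train_loss[3], h$train_loss[1])
  }
  expect_error(train_config(optimizer = "rmsprop"), class = "medtext_usage_error")
})

test_that("non-finite losses abort with the failing epoch and batch", {
  corp <- generate_corpus(synth_spec(n_docs = 40, doc_len = c(5, 8), seed = 17))
  wv <- build_vocab(corp, "word")
  tr <- encode_corpus(corp, wv, 8)
  emb <- random_embedding(wv, 4, seed = 1)
  m <- build_bigru_mha(emb, n_classes = 2, n_w = 8, widths = 1, n_filters = 2,
                       hidden = 2, layers = 1, n_heads = 1, seed = 3)
  m$params$dense$W[1, 1] <- NaN
  expect_error(train_model(m, tr, NULL, train_config(batch_size = 16, epochs = 1)),
               "epoch 1, batch 1", class = "medtext_training_error")
})

test_that("evaluation is invariant to test-set order and composes the pipeline", {
  corp <- generate_corpus(synth_spec(n_docs = 50, doc_len = c(5, 10), seed = 19))
  wv <- build_vocab(corp, "word")
  b <- encode_corpus(corp, wv, 10)
  emb <- random_embedding(wv, 5, seed = 1)
  m <- build_bigru_mha(emb, n_classes = 2, n_w = 10, widths = c(1, 2),
                       n_filters = 2, hidden = 3, layers = 1, n_heads = 2, seed = 4)
  m1 <- evaluate_model(m, b)
  perm <- sample(50)
  m2 <- evaluate_model(m, medtext:::subset_batch(b, perm))
  expect_equal(m1, m2)
  # compositional oracle: run the three stages by hand
  pred <- predict_labels(m, b)
  expect_equal(m1, metrics_from_counts(confusion_counts(pred, b$labels, 2)))
})

test_that("grid sweeps cover the axis, mark the best row, and survive failures", {
  corp <- generate_corpus(synth_spec(n_docs = 80, doc_len = c(5, 10),
                                     keyword_rate = 0.3, seed = 23))
  spl <- split_corpus(corp, seed = 1)
  wv <- build_vocab(spl$train, "word")
  data <- list(train = encode_corpus(spl$train, wv, 10),
               val = encode_corpus(spl$val, wv, 10),
               test = encode_corpus(spl$test, wv, 10),
               emb = random_embedding(wv, 5, seed = 1), tag = "synthetic")
  base <- list(n_classes = 2, n_w = 10, widths = c(1, 2), n_filters = 2,
               hidden = 2, layers = 1, n_heads = 2, dropout = 0.2, seed = 4,
               config = train_config(batch_size = 32, epochs = 1, seed = 9))
  sw <- grid_sweep("bigru_mha", "learning_rate", c(0.05, 0.01), data, base)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$value, c("0.05", "0.01"))
  expect_equal(sum(sw$best), 1)
  ok <- which(!sw$failed)
  expect_equal(which(sw$best), ok[which.max(sw$accuracy[ok])])
  sw2 <- grid_sweep("bigru_mha", "learning_rate", c(0.05, 0.01), data, base)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
  # a failing cell is recorded and the sweep continues
  sw3 <- grid_sweep("bigru_mha", "activation", c("sigmoid", "not_an_activation"),
                    data, base)
  expect_equal(sw3$failed, c(FALSE, TRUE))
  expect_true(is.na(sw3$accuracy[2]))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_sweep(sw, tmp)
  expect_equal(nrow(utils::read.delim(tmp)), 2)
})

test_that("tidy, glance and autoplot expose the training results", {
  corp <- generate_corpus(synth_spec(n_docs = 40, doc_len = c(5, 8), seed = 29))
  wv <- build_vocab(corp, "word")
  tr <- encode_corpus(corp, wv, 8)
  emb <- random_embedding(wv, 4, seed = 1)
  m <- train_model(build_bigru_mha(emb, n_classes = 2, n_w = 8, widths = 1,
                                   n_filters = 2, hidden = 2, layers = 1,
                                   n_heads = 1, seed = 3),
                   tr, tr, train_config(batch_size = 16, epochs = 2, seed = 1))
  td <- tidy(m)
  expect_equal(td$epoch, seq_len(nrow(td)))
  g <- glance(m)
  expect_equal(g$model, "bigru_mha")
  expect_equal(g$n_params, param_count(m))
  expect_s3_class(autoplot(m), "ggplot")
})
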