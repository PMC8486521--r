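#' Training configuration
#'
#' @param batch_size Minibatch size (default 512).
#' @param optimizer One of `"adam"`, `"sgd"`, `"nadam"`, `"adagrad"`.
#' @param lr Learning rate (default 0.01).
#' @param epochs Maximum epochs (default 10).
#' @param patience Early-stopping patience on validation accuracy
#'   (default 5).
#' @param dropout Optional override of the model's dropout rate.
#' @param seed Seed driving shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 512L, optimizer = "adam", lr = 0.01,
                         epochs = 10L, patience = 5L, dropout = NULL,
                         seed = 1L) {
  check_scalar_number(batch_size, "batch_size", lower = 1)
  check_scalar_number(lr, "lr", lower = 0)
  check_scalar_number(epochs, "epochs", lower = 1)
  check_scalar_number(patience, "patience", lower = 1)
  if (!optimizer %in% c("adam", "sgd", "nadam", "adagrad")) {
    stop_usage(sprintf("unknown optimizer '%s'", optimizer))
  }
  structure(list(batch_size = as.integer(batch_size), optimizer = optimizer,
                 lr = lr, epochs = as.integer(epochs),
                 patience = as.integer(patience), dropout = dropout,
                 seed = as.integer(seed)),
            class = "train_config")
}

batch_accuracy <- function(model, batch) {
  mean(predict_labels(model, batch) == batch$labels)
}

#' Train a model by minibatch gradient descent
#'
#' Minimizes the cross-entropy loss with the configured optimizer. All
#' randomness — minibatch shuffling, dropout masks — derives from
#' `config$seed`, so identical seeds give identical histories. Training
#' stops early when the validation accuracy has not improved for
#' `config$patience` epochs (or has reached 1), and the parameters of the
#' best validation epoch are restored.
#'
#' @param model A model from [build_qc_lstm()] or [build_bigru_mha()].
#' @param train_batch,val_batch `encoded_batch` objects (validation batch
#'   optional).
#' @param config A [train_config()].
#' @return The trained model; its `history` element is a tibble with one row
#'   per epoch (`epoch`, `train_loss`, `val_accuracy`).
#' @export
train_model <- function(model, train_batch, val_batch = NULL,
                        config = train_config()) {
  if (!inherits(model, "medtext_model")) stop_validation("not a medtext model")
  if (!is.null(config$dropout)) model$spec$dropout <- config$dropout
  n <- nrow(train_batch$word)
  opt <- make_optimizer(config$optimizer, config$lr)
  state_env <- new.env(parent = emptyenv())
  history <- list()
  best_acc <- -Inf
  best_params <- NULL
  stall <- 0L
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      total_loss <- 0
      for (bi in seq_along(starts)) {
        rows <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        mb <- subset_batch(train_batch, rows)
        fwd <- model_fwd(model, mb, training = TRUE)
        loss <- cross_entropy_loss(fwd$P, mb$labels)
        if (!is.finite(loss)) {
          abort_medtext(sprintf("non-finite loss at epoch %d, batch %d", ep, bi),
                        "medtext_training_error")
        }
        total_loss <- total_loss + loss * length(rows)
        grads <- model_bwd(model, fwd, mb$labels)
        model$params <- walk_update(model$params, grads, opt, state_env)
      }
      val_acc <- if (is.null(val_batch)) NA_real_ else batch_accuracy(model, val_batch)
      history[[ep]] <- tibble::tibble(epoch = ep,
                                      train_loss = total_loss / n,
                                      val_accuracy = val_acc)
      if (!is.null(val_batch)) {
        if (val_acc > best_acc + 1e-12) {
          best_acc <- val_acc
          best_params <- model$params
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
        if (stall >= config$patience || val_acc >= 1 - 1e-12) break
      }
    }
  })
  if (!is.null(best_params)) model$params <- best_params
  model$history <- dplyr::bind_rows(history)
  model$config <- config
  model
}

#' Predict class labels
#'
#' Argmax over the forward probabilities, ties broken toward the lowest
#' class index.
#'
#' @param model A trained (or initialized) model.
#' @param batch An `encoded_batch`.
#' @return Integer vector of 0-based labels.
#' @export
predict_labels <- function(model, batch) {
  P <- model_fwd(model, batch, training = FALSE)$P
  max.col(P, ties.method = "first") - 1L
}

#' Evaluate a model on a test set
#'
#' Composition of [predict_labels()], [confusion_counts()] and
#' [metrics_from_counts()].
#'
#' @param model A model.
#' @param batch Encoded test set (non-empty).
#' @param average Averaging mode for multiclass metrics.
#' @return One-row metrics tibble (percentages).
#' @export
evaluate_model <- function(model, batch, average = "macro") {
  if (!nrow(batch$word)) stop_validation("test set is empty")
  pred <- predict_labels(model, batch)
  counts <- confusion_counts(pred, batch$labels, length(batch$classes))
  metrics_from_counts(counts, average = average)
}
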