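#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a model
#'
#' @param x A trained model.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_accuracy`.
#' @export
tidy.medtext_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(0), train_loss = numeric(0),
                                val_accuracy = numeric(0))
}

#' One-row summary of a model
#'
#' @param x A model.
#' @param ... Unused.
#' @return Tibble with `model`, `n_params`, `epochs_trained`,
#'   `final_train_loss`, `best_val_accuracy`.
#' @export
glance.medtext_model <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(
    model = x$type,
    n_params = param_count(x),
    epochs_trained = nrow(h),
    final_train_loss = if (nrow(h)) h$train_loss[nrow(h)] else NA_real_,
    best_val_accuracy = if (nrow(h) && any(is.finite(h$val_accuracy)))
      max(h$val_accuracy, na.rm = TRUE) else NA_real_
  )
}
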