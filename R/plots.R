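#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training history
#'
#' Training loss and validation accuracy against the epoch index.
#'
#' @param object A trained model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.medtext_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("train_loss", "val_accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = object$type) +
    ggplot2::theme_minimal()
}

#' Plot a hyperparameter sweep
#'
#' Test accuracy per axis value, best cell highlighted.
#'
#' @param object A `sweep_result` from [grid_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- object[!object$failed, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$accuracy,
                                   fill = .data$best)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$dataset)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#2c7fb8"),
                               guide = "none") +
    ggplot2::labs(x = unique(object$axis), y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
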