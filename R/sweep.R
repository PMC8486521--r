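#' Hyperparameter grid sweep
#'
#' Trains and evaluates one model per value of a single hyperparameter axis,
#' all other settings held at `base`, with the same seed in every cell, and
#' returns one row per value in input order with the best row (by test
#' accuracy) marked. A cell that errors is recorded as a failed row and the
#' sweep continues.
#'
#' @param family `"qc_lstm"` or `"bigru_mha"`.
#' @param axis One of `"kernel_widths"`, `"learning_rate"`, `"dropout"`,
#'   `"optimizer"`, `"activation"`, `"bigru_layers"`.
#' @param values List (or vector) of axis values, e.g.
#'   `list(c(1, 3), c(1, 3, 5))` for kernel widths.
#' @param data List with encoded `train`, `val`, `test` batches, the
#'   embeddings (`word_emb` and `char_emb` for `qc_lstm`, `emb` for
#'   `bigru_mha`), and optionally a `tag` naming the dataset.
#' @param base List of baseline settings passed to the model builder
#'   (`widths`, `n_filters`, `hidden`, `layers`, `n_heads`, `dropout`,
#'   `activation`, `seed`, ...) plus a `config` [train_config()].
#' @return A `sweep_result` tibble with columns `axis`, `value`, `dataset`,
#'   `accuracy`, `precision`, `recall`, `f1`, `best`, `failed`.
#' @export
grid_sweep <- function(family = c("qc_lstm", "bigru_mha"), axis, values,
                       data, base = list()) {
  family <- match.arg(family)
  axes <- c("kernel_widths", "learning_rate", "dropout", "optimizer",
            "activation", "bigru_layers")
  if (!axis %in% axes) {
    stop_usage(sprintf("unknown sweep axis '%s'", axis))
  }
  if (!length(values)) stop_validation("`values` must be non-empty")
  if (axis == "bigru_layers" && family != "bigru_mha") {
    stop_usage("axis 'bigru_layers' applies only to the bigru_mha family")
  }
  values <- if (is.list(values)) values else as.list(values)
  tag <- data$tag %||% "synthetic"
  base_config <- base$config %||% train_config()
  rows <- lapply(values, function(v) {
    build_args <- base[setdiff(names(base), "config")]
    config <- base_config
    switch(axis,
      kernel_widths = { build_args$widths <- v },
      learning_rate = { config$lr <- v },
      dropout = { build_args$dropout <- v; config$dropout <- v },
      optimizer = { config$optimizer <- v },
      activation = { build_args$activation <- v },
      bigru_layers = { build_args$layers <- v }
    )
    res <- tryCatch({
      model <- if (family == "qc_lstm") {
        do.call(build_qc_lstm, c(list(word_emb = data$word_emb,
                                      char_emb = data$char_emb),
                                 build_args))
      } else {
        do.call(build_bigru_mha, c(list(emb = data$emb), build_args))
      }
      trained <- train_model(model, data$train, data$val, config)
      evaluate_model(trained, data$test)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(axis = axis, value = format_axis_value(v), dataset = tag,
                     accuracy = NA_real_, precision = NA_real_,
                     recall = NA_real_, f1 = NA_real_, failed = TRUE)
    } else {
      tibble::tibble(axis = axis, value = format_axis_value(v), dataset = tag,
                     accuracy = res$accuracy, precision = res$precision,
                     recall = res$recall, f1 = res$f1, failed = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$best <- FALSE
  ok <- which(!out$failed)
  if (length(ok)) out$best[ok[which.max(out$accuracy[ok])]] <- TRUE
  class(out) <- c("sweep_result", class(out))
  out
}

format_axis_value <- function(v) {
  if (length(v) > 1L) paste0("[", paste(v, collapse = ","), "]") else as.character(v)
}

#' Write a sweep table as a delimited file
#'
#' @param sweep A `sweep_result`.
#' @param path Output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(as.data.frame(sweep)[, c("axis", "value", "dataset",
                                              "accuracy", "precision",
                                              "recall", "f1")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
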