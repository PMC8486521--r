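# Parameter-tree utilities: every model's weights live in a nested named
# list whose numeric leaves are the trainable arrays. Gradient trees
# produced by the backward passes mirror exactly the trainable subset of
# that structure, so the optimizer and the serializer can walk them
# generically.

trainable_names <- function(p) {
  cls <- class(p)[1]
  switch(cls,
    lstm_params = c("W_z", "b_z", "W_i", "b_i", "W_f", "b_f", "W_o", "b_o"),
    gru_params = c("W_z", "W_r", "W"),
    bigru_params = c("forward", "backward"),
    conv_bank = "filters",
    hybrid_attention_params = c("W_r", "v_a", "b"),
    multihead_params = c("heads", "W_o"),
    dense_params = c("W", "b"),
    NULL
  )
}

# Flatten the trainable leaves of a parameter tree to a named list of
# numeric arrays, with "/"-joined path names.
flatten_params <- function(p, path = "") {
  if (is.numeric(p)) {
    out <- list(p)
    names(out) <- path
    return(out)
  }
  if (!is.list(p)) return(list())
  nms <- trainable_names(p) %||% names(p) %||% as.character(seq_along(p))
  if (is.null(names(p))) {
    idx <- seq_along(p)
  } else {
    idx <- nms
  }
  out <- list()
  for (i in seq_along(idx)) {
    key <- idx[i]
    child <- p[[key]]
    sub <- flatten_params(child, paste0(path, if (nzchar(path)) "/" else "",
                                        if (is.character(key)) key else paste0("[", key, "]")))
    out <- c(out, sub)
  }
  out
}

#' Count trainable parameters of a model
#'
#' @param model A model from [build_qc_lstm()] or [build_bigru_mha()] (or any
#'   nested parameter list).
#' @return Total number of trainable scalar parameters.
#' @export
param_count <- function(model) {
  p <- if (!is.null(model$params)) model$params else model
  sum(vapply(flatten_params(p), length, 0L))
}

#' Save model parameters as a JSON manifest
#'
#' Writes a flat named-array container: one JSON record per trainable leaf
#' with its path, dimensions and values, in deterministic traversal order.
#'
#' @param model A model (or a bare parameter tree).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_params <- function(model, path) {
  p <- if (!is.null(model$params)) model$params else model
  fl <- flatten_params(p)
  recs <- lapply(names(fl), function(nm) {
    v <- fl[[nm]]
    list(name = nm, dim = if (is.matrix(v)) dim(v) else length(v),
         data = as.vector(v))
  })
  jsonlite::write_json(recs, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Load parameters saved by [save_params()] into a model
#'
#' The model must have the same architecture (identical traversal order,
#' names and shapes) as the one the file was saved from.
#'
#' @param model Target model.
#' @param path File written by [save_params()].
#' @return The model with its parameters replaced.
#' @export
load_params <- function(model, path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  has_params <- !is.null(model$params)
  p <- if (has_params) model$params else model
  fl <- flatten_params(p)
  if (length(fl) != nrow(recs)) stop_validation("parameter file does not match model structure")
  values <- stats::setNames(vector("list", nrow(recs)),
                            vapply(recs$name, as.character, ""))
  for (i in seq_len(nrow(recs))) {
    nm <- as.character(recs$name[[i]])
    tmpl <- fl[[nm]]
    if (is.null(tmpl)) stop_validation(sprintf("unknown parameter '%s' in file", nm))
    v <- as.numeric(recs$data[[i]])
    if (length(v) != length(tmpl)) {
      stop_validation(sprintf("shape mismatch for parameter '%s'", nm))
    }
    if (is.matrix(tmpl)) v <- matrix(v, nrow(tmpl), ncol(tmpl))
    values[[nm]] <- v
  }
  p2 <- assign_leaves(p, values, "")
  if (has_params) {
    model$params <- p2
    model
  } else {
    p2
  }
}

assign_leaves <- function(p, values, path) {
  if (is.numeric(p)) {
    return(values[[path]] %||% p)
  }
  if (!is.list(p)) return(p)
  nms <- trainable_names(p) %||% names(p) %||% as.character(seq_along(p))
  keys <- if (is.null(names(p))) seq_along(p) else nms
  for (i in seq_along(keys)) {
    key <- keys[i]
    sub_path <- paste0(path, if (nzchar(path)) "/" else "",
                       if (is.character(key)) key else paste0("[", key, "]"))
    p[[key]] <- assign_leaves(p[[key]], values, sub_path)
  }
  p
}

# Walk a gradient tree (mirroring the trainable structure of `params`) and
# apply `fun(value, grad, state)` to every leaf. `fun` returns
# list(value, state). Optimizer state is keyed by path in `state_env`.
walk_update <- function(params, grads, fun, state_env, path = "") {
  keys <- if (is.null(names(grads))) seq_along(grads) else names(grads)
  for (i in seq_along(keys)) {
    key <- keys[i]
    g <- grads[[key]]
    if (is.null(g)) next
    sub_path <- paste0(path, "/", if (is.character(key)) key else paste0("[", key, "]"))
    if (is.list(g)) {
      params[[key]] <- walk_update(params[[key]], g, fun, state_env, sub_path)
    } else {
      res <- fun(params[[key]], g, state_env[[sub_path]])
      params[[key]] <- res$value
      state_env[[sub_path]] <- res$state
    }
  }
  params
}

make_optimizer <- function(name, lr) {
  eps <- 1e-8
  switch(name,
    sgd = function(v, g, s) list(value = v - lr * g, state = NULL),
    adagrad = function(v, g, s) {
      G <- (s %||% 0) + g^2
      list(value = v - lr * g / sqrt(G + eps), state = G)
    },
    adam = function(v, g, s) {
      s <- s %||% list(m = 0, v = 0, t = 0)
      s$t <- s$t + 1
      s$m <- 0.9 * s$m + 0.1 * g
      s$v <- 0.999 * s$v + 0.001 * g^2
      mh <- s$m / (1 - 0.9^s$t)
      vh <- s$v / (1 - 0.999^s$t)
      list(value = v - lr * mh / (sqrt(vh) + eps), state = s)
    },
    nadam = function(v, g, s) {
      s <- s %||% list(m = 0, v = 0, t = 0)
      s$t <- s$t + 1
      s$m <- 0.9 * s$m + 0.1 * g
      s$v <- 0.999 * s$v + 0.001 * g^2
      mh <- s$m / (1 - 0.9^(s$t + 1))
      vh <- s$v / (1 - 0.999^s$t)
      upd <- 0.9 * mh + 0.1 * g / (1 - 0.9^s$t)
      list(value = v - lr * upd / (sqrt(vh) + eps), state = s)
    },
    stop_usage(sprintf("unknown optimizer '%s'", name))
  )
}
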