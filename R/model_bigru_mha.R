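#' Build the hybrid BiGRU classifier with multihead self-attention
#'
#' Two parallel branches over the word-embedded sequence:
#' \enumerate{
#'   \item a convolution branch (widths in `widths`), reduced by global max
#'     AND average pooling, concatenated;
#'   \item a stack of `layers` bidirectional GRUs followed by multihead
#'     self-attention (`Q = K = V =` the BiGRU output sequence), itself
#'     reduced by max and average pooling over positions.
#' }
#' The concatenated branch features pass through dropout and a dense softmax
#' layer. Character-level input is not used by this architecture.
#'
#' @param emb Word-level `embedding_matrix`.
#' @param n_classes Number of classes.
#' @param n_w Word sequence length the model expects.
#' @param widths Convolution filter widths (default `c(1, 3, 5)`).
#' @param n_filters Filters per width (default 200).
#' @param hidden GRU hidden units per direction (default 128).
#' @param layers Stacked BiGRU layers (default 2).
#' @param n_heads Attention heads; must divide `2 * hidden` (default 8).
#' @param dropout Dropout rate before the dense layer (default 0.4).
#' @param activation Convolution activation (default `"sigmoid"`).
#' @param mha_init `"uniform"` or `"identity"` (single head only; used for
#'   reduction tests).
#' @param train_embeddings Update the embedding during training.
#' @param seed Seed for weight initialization.
#' @return A `bigru_mha` model object.
#' @export
build_bigru_mha <- function(emb, n_classes, n_w = NULL,
                            widths = c(1L, 3L, 5L), n_filters = 200L,
                            hidden = 128L, layers = 2L, n_heads = 8L,
                            dropout = 0.4, activation = "sigmoid",
                            mha_init = "uniform",
                            train_embeddings = TRUE, seed = 1L) {
  check_scalar_number(n_classes, "n_classes", lower = 2)
  check_scalar_number(layers, "layers", lower = 1)
  check_scalar_number(dropout, "dropout", lower = 0, upper = 0.999)
  if (!inherits(emb, "embedding_matrix")) {
    stop_validation("`emb` must be an `embedding_matrix`")
  }
  m <- 2L * as.integer(hidden)
  if (m %% n_heads != 0L) {
    stop_validation("2 * hidden must be divisible by n_heads")
  }
  if (!is.null(n_w) && any(widths > n_w)) {
    stop_validation("filter widths must not exceed the sequence length")
  }
  activation_fn(activation)
  d <- emb$d
  bigru <- lapply(seq_len(layers), function(l) {
    bigru_params(if (l == 1L) d else m, hidden,
                 seed = derive_seed(seed, paste0("bigru", l)))
  })
  params <- list(
    emb = unname(emb$matrix),
    conv = conv_bank(widths, n_filters, d, activation,
                     seed = derive_seed(seed, "conv")),
    bigru = bigru,
    mha = multihead_params(n_heads, m, init = mha_init,
                           seed = derive_seed(seed, "mha")),
    dense = dense_params(2L * n_filters * length(widths) + 2L * m, n_classes,
                         seed = derive_seed(seed, "dense"))
  )
  spec <- list(type = "bigru_mha", n_classes = as.integer(n_classes),
               widths = as.integer(widths), n_filters = as.integer(n_filters),
               hidden = as.integer(hidden), layers = as.integer(layers),
               n_heads = as.integer(n_heads), dropout = dropout,
               activation = activation, n_w = n_w,
               train_embeddings = isTRUE(train_embeddings),
               vocab = nrow(emb$matrix), d = d)
  structure(list(type = "bigru_mha", spec = spec, params = params,
                 history = NULL),
            class = c("bigru_mha", "medtext_model"))
}

bigru_mha_fwd <- function(model, batch, training = FALSE) {
  sp <- model$spec
  p <- model$params
  idx <- batch$word
  if (any(idx >= sp$vocab)) stop_validation("word index out of vocabulary range")
  A <- bemb_fwd(idx, p$emb)
  B <- dim(A)[1]
  # CNN branch: max and average pooling, concatenated
  cv <- bconv_fwd(A, p$conv)
  maxp <- lapply(cv$maps, bpool_max_fwd)
  cnn_feat <- cbind(do.call(cbind, lapply(maxp, `[[`, "out")),
                    do.call(cbind, lapply(cv$maps, bpool_avg_fwd)))
  # BiGRU stack -> multihead self-attention -> max+avg pooling
  Ys <- vector("list", sp$layers)
  inp <- A
  for (l in seq_len(sp$layers)) {
    Ys[[l]] <- bbigru_fwd(inp, p$bigru[[l]])
    inp <- Ys[[l]]$Y
  }
  mh <- bmha_fwd(inp, p$mha)
  amax <- bpool_max_fwd(mh$out)
  aavg <- bpool_avg_fwd(mh$out)
  attn_feat <- cbind(amax$out, aavg)
  final <- cbind(cnn_feat, attn_feat)
  dp <- if (training && sp$dropout > 0) bdropout_fwd(final, sp$dropout) else
    list(out = final, mask = NULL)
  P <- bdense_fwd(dp$out, p$dense)
  list(P = P, cache = list(idx = idx, A = A, cv = cv, maxp = maxp,
                           Ys = Ys, mh = mh, amax = amax,
                           final = final, hdrop = dp$out, mask = dp$mask))
}

bigru_mha_bwd <- function(model, fwd, y) {
  sp <- model$spec
  p <- model$params
  ca <- fwd$cache
  dd <- bdense_bwd(fwd$P, y, ca$hdrop, p$dense)
  dfinal <- bdropout_bwd(dd$dH, ca$mask)
  nconv <- sp$n_filters * length(sp$widths)
  m <- 2L * sp$hidden
  dcnn <- dfinal[, seq_len(2L * nconv), drop = FALSE]
  dattn <- dfinal[, 2L * nconv + seq_len(2L * m), drop = FALSE]
  # conv branch
  dmaps <- vector("list", length(sp$widths))
  for (wi in seq_along(sp$widths)) {
    cols <- (wi - 1L) * sp$n_filters + seq_len(sp$n_filters)
    dims <- dim(ca$cv$maps[[wi]])
    dmax <- bpool_max_bwd(dcnn[, cols, drop = FALSE], ca$maxp[[wi]]$arg, dims)
    davg <- bpool_avg_bwd(dcnn[, nconv + cols, drop = FALSE], dims)
    dmaps[[wi]] <- dmax + davg
  }
  cb <- bconv_bwd(dmaps, ca$cv$cache, p$conv)
  # attention branch
  dims_o <- dim(ca$mh$out)
  dmh <- bpool_max_bwd(dattn[, seq_len(m), drop = FALSE], ca$amax$arg, dims_o) +
    bpool_avg_bwd(dattn[, m + seq_len(m), drop = FALSE], dims_o)
  mb <- bmha_bwd(dmh, ca$mh$cache, p$mha)
  dY <- mb$dA
  bigru_grads <- vector("list", sp$layers)
  for (l in rev(seq_len(sp$layers))) {
    inp <- if (l == 1L) ca$A else ca$Ys[[l - 1L]]$Y
    gb <- bbigru_bwd(dY, ca$Ys[[l]], p$bigru[[l]], dim(inp))
    bigru_grads[[l]] <- gb$grads
    dY <- gb$dA
  }
  dA <- cb$dA + dY
  grads <- list(dense = dd$grads,
                conv = list(filters = cb$filters),
                bigru = bigru_grads,
                mha = mb$grads)
  if (sp$train_embeddings) grads$emb <- bemb_bwd(dA, ca$idx, sp$vocab)
  grads
}

#' Forward pass of the hybrid BiGRU / multihead-attention model
#'
#' Evaluation-mode forward pass (dropout disabled): deterministic given the
#' parameters and inputs.
#'
#' @param model A `bigru_mha` model.
#' @param batch An `encoded_batch` (word-level encoding only).
#' @return Probability matrix `[n_docs x n_classes]`; rows sum to 1.
#' @export
bigru_mha_forward <- function(model, batch) {
  bigru_mha_fwd(model, batch, training = FALSE)$P
}

# Dispatch helpers shared by the training engine.
model_fwd <- function(model, batch, training = FALSE) {
  switch(model$type,
         qc_lstm = qc_fwd(model, batch, training),
         bigru_mha = bigru_mha_fwd(model, batch, training),
         stop_usage(sprintf("unknown model type '%s'", model$type)))
}

model_bwd <- function(model, fwd, y) {
  switch(model$type,
         qc_lstm = qc_bwd(model, fwd, y),
         bigru_mha = bigru_mha_bwd(model, fwd, y))
}
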