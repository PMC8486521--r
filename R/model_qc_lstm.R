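#' Build the quad-channel hybrid LSTM classifier
#'
#' The model runs four parallel channels — \{word, char\} embeddings each
#' feeding a convolution branch and an LSTM branch. Per level,
#' `channel(x) = conv(x) (+) LSTM(x)`: the convolution branch (widths in
#' `widths`, `n_filters` filters each) is reduced by global max pooling over
#' time, and the LSTM branch's per-step hidden and cell states are combined
#' by hybrid (additive) attention into a context vector. The concatenated
#' channel outputs pass through dropout and a dense softmax layer.
#'
#' @param word_emb,char_emb `embedding_matrix` objects for the two levels
#'   (either may be omitted by restricting `channels`).
#' @param n_classes Number of classes (>= 2).
#' @param n_w,n_c Word / character sequence lengths the model expects.
#' @param widths Convolution filter widths (default `c(1, 3, 5)`).
#' @param n_filters Filters per width per channel (default 200).
#' @param hidden LSTM hidden units per channel (default 128).
#' @param attn_dim Attention projection dimension (default `hidden`).
#' @param dropout Dropout rate on the merged hidden vector (default 0.5).
#' @param activation Convolution activation (default `"relu"`).
#' @param channels Which embedding levels to use; the default is the full
#'   quad-channel configuration, `c("word")` is the word-channels-only
#'   ablation.
#' @param train_embeddings Update embeddings during training (default TRUE).
#' @param seed Seed for weight initialization.
#' @return A `qc_lstm` model object.
#' @export
build_qc_lstm <- function(word_emb = NULL, char_emb = NULL, n_classes,
                          n_w = NULL, n_c = NULL,
                          widths = c(1L, 3L, 5L), n_filters = 200L,
                          hidden = 128L, attn_dim = NULL, dropout = 0.5,
                          activation = "relu", channels = c("word", "char"),
                          train_embeddings = TRUE, seed = 1L) {
  check_scalar_number(n_classes, "n_classes", lower = 2)
  check_scalar_number(dropout, "dropout", lower = 0, upper = 0.999)
  if (!length(channels) || !all(channels %in% c("word", "char"))) {
    stop_validation("`channels` must be a subset of c('word', 'char')")
  }
  attn_dim <- attn_dim %||% hidden
  activation_fn(activation)  # validate the name early
  params <- list()
  spec <- list(type = "qc_lstm", n_classes = as.integer(n_classes),
               widths = as.integer(widths), n_filters = as.integer(n_filters),
               hidden = as.integer(hidden), attn_dim = as.integer(attn_dim),
               dropout = dropout, activation = activation,
               channels = channels, train_embeddings = isTRUE(train_embeddings),
               n_w = n_w, n_c = n_c, dims = list())
  feat_len <- 0L
  for (lvl in channels) {
    emb <- if (lvl == "word") word_emb else char_emb
    max_len <- if (lvl == "word") n_w else n_c
    if (is.null(emb)) stop_validation(sprintf("missing %s-level embedding", lvl))
    if (!inherits(emb, "embedding_matrix")) {
      stop_validation("embeddings must be `embedding_matrix` objects")
    }
    if (!is.null(max_len) && any(widths > max_len)) {
      stop_validation("filter widths must not exceed the sequence length")
    }
    d <- emb$d
    params[[paste0("emb_", lvl)]] <- unname(emb$matrix)
    params[[paste0(lvl, "_conv")]] <- conv_bank(widths, n_filters, d, activation,
                                                seed = derive_seed(seed, paste0(lvl, "conv")))
    params[[paste0(lvl, "_lstm")]] <- lstm_params(d, hidden,
                                                  seed = derive_seed(seed, paste0(lvl, "lstm")))
    params[[paste0(lvl, "_attn")]] <- hybrid_attention_params(2L * hidden, attn_dim,
                                                              seed = derive_seed(seed, paste0(lvl, "attn")))
    spec$dims[[lvl]] <- list(vocab = nrow(emb$matrix), d = d)
    feat_len <- feat_len + n_filters * length(widths) + 2L * hidden
  }
  params$dense <- dense_params(feat_len, n_classes, seed = derive_seed(seed, "dense"))
  structure(list(type = "qc_lstm", spec = spec, params = params,
                 history = NULL),
            class = c("qc_lstm", "medtext_model"))
}

#' @export
print.medtext_model <- function(x, ...) {
  cat(sprintf("<%s> %d classes, %s trainable parameters%s\n",
              x$type, x$spec$n_classes,
              format(param_count(x), big.mark = ","),
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

# Batched forward pass. With `training = FALSE` no random number is drawn
# and the output is bitwise reproducible.
qc_fwd <- function(model, batch, training = FALSE) {
  sp <- model$spec
  p <- model$params
  caches <- list()
  feats <- list()
  for (lvl in sp$channels) {
    idx <- if (lvl == "word") batch$word else batch$char
    if (is.null(idx)) stop_validation(sprintf("batch lacks %s-level encoding", lvl))
    if (any(idx >= sp$dims[[lvl]]$vocab)) {
      stop_validation(sprintf("%s index out of vocabulary range", lvl))
    }
    A <- bemb_fwd(idx, p[[paste0("emb_", lvl)]])
    cv <- bconv_fwd(A, p[[paste0(lvl, "_conv")]])
    pools <- lapply(cv$maps, bpool_max_fwd)
    convfeat <- do.call(cbind, lapply(pools, `[[`, "out"))
    ls <- blstm_fwd(A, p[[paste0(lvl, "_lstm")]])
    B <- dim(A)[1]; T_ <- dim(A)[2]; H <- sp$hidden
    Hcat <- array(0, c(B, T_, 2L * H))
    for (t in seq_len(T_)) {
      Hcat[, t, seq_len(H)] <- ls$Hs[[t]]
      Hcat[, t, H + seq_len(H)] <- ls$Cs[[t]]
    }
    at <- bhattn_fwd(Hcat, p[[paste0(lvl, "_attn")]])
    feats[[lvl]] <- cbind(convfeat, at$out)
    caches[[lvl]] <- list(idx = idx, A = A, cv = cv, pools = pools,
                          ls = ls, at = at, T_ = T_)
  }
  # merge order: char-level channel pair first, then word-level
  ord <- intersect(c("char", "word"), sp$channels)
  h <- do.call(cbind, feats[ord])
  dp <- if (training && sp$dropout > 0) bdropout_fwd(h, sp$dropout) else list(out = h, mask = NULL)
  P <- bdense_fwd(dp$out, p$dense)
  list(P = P, cache = list(channels = caches, h = h, hdrop = dp$out,
                           mask = dp$mask, ord = ord))
}

qc_bwd <- function(model, fwd, y) {
  sp <- model$spec
  p <- model$params
  dd <- bdense_bwd(fwd$P, y, fwd$cache$hdrop, p$dense)
  dh <- bdropout_bwd(dd$dH, fwd$cache$mask)
  grads <- list(dense = dd$grads)
  off <- 0L
  nconv <- sp$n_filters * length(sp$widths)
  H <- sp$hidden
  for (lvl in fwd$cache$ord) {
    ch <- fwd$cache$channels[[lvl]]
    seg <- dh[, off + seq_len(nconv + 2L * H), drop = FALSE]
    off <- off + nconv + 2L * H
    dconv <- seg[, seq_len(nconv), drop = FALSE]
    dctx <- seg[, nconv + seq_len(2L * H), drop = FALSE]
    # conv branch
    dmaps <- vector("list", length(sp$widths))
    for (wi in seq_along(sp$widths)) {
      cols <- (wi - 1L) * sp$n_filters + seq_len(sp$n_filters)
      dims <- dim(ch$cv$maps[[wi]])
      dmaps[[wi]] <- bpool_max_bwd(dconv[, cols, drop = FALSE],
                                   ch$pools[[wi]]$arg, dims)
    }
    cb <- bconv_bwd(dmaps, ch$cv$cache, p[[paste0(lvl, "_conv")]])
    # attention + LSTM branch
    ab <- bhattn_bwd(dctx, ch$at$cache, p[[paste0(lvl, "_attn")]])
    T_ <- ch$T_
    B <- dim(ab$dA)[1]
    dHs <- lapply(seq_len(T_), function(t) matrix(ab$dA[, t, seq_len(H)], B, H))
    dCs <- lapply(seq_len(T_), function(t) matrix(ab$dA[, t, H + seq_len(H)], B, H))
    lb <- blstm_bwd(dHs, dCs, ch$ls$cache, p[[paste0(lvl, "_lstm")]], dim(ch$A))
    dA <- cb$dA + lb$dA
    grads[[paste0(lvl, "_conv")]] <- list(filters = cb$filters)
    grads[[paste0(lvl, "_attn")]] <- ab$grads
    grads[[paste0(lvl, "_lstm")]] <- lb$grads
    if (sp$train_embeddings) {
      grads[[paste0("emb_", lvl)]] <- bemb_bwd(dA, ch$idx, sp$dims[[lvl]]$vocab)
    }
  }
  grads
}

#' Forward pass of the quad-channel LSTM model
#'
#' Evaluation-mode forward pass (dropout disabled): deterministic given the
#' parameters and inputs.
#'
#' @param model A `qc_lstm` model.
#' @param batch An `encoded_batch` with the encodings the model's channels
#'   need.
#' @return Probability matrix `[n_docs x n_classes]`; rows sum to 1.
#' @export
qc_forward <- function(model, batch) {
  qc_fwd(model, batch, training = FALSE)$P
}
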