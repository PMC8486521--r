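# Layer-level forward computations, written as pure single-instance
# operations so each one can be checked against a brute-force oracle.
# The batched training engine in layers-batch.R reuses the same parameter
# containers.

glorot_limit <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

init_mat <- function(nr, nc, init) {
  if (init == "zero") return(matrix(0, nr, nc))
  lim <- glorot_limit(nc, nr)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' LSTM parameter bundle
#'
#' Four weight matrices of shape `[hidden x (hidden + input_dim)]` acting on
#' the concatenation `[h_{t-1}, x_t]`, plus four bias vectors, for the
#' candidate (`z`, tanh) and the input/forget/output sigmoid gates.
#'
#' @param input_dim Input dimension.
#' @param hidden Number of hidden units.
#' @param init `"zero"` or `"uniform"` (Glorot-uniform, seeded).
#' @param seed Seed for `"uniform"` initialization.
#' @return An `lstm_params` list.
#' @export
lstm_params <- function(input_dim, hidden, init = c("uniform", "zero"), seed = 1L) {
  init <- match.arg(init)
  nc <- hidden + input_dim
  withr::with_seed(as.integer(seed), {
    p <- list(
      W_z = init_mat(hidden, nc, init), b_z = numeric(hidden),
      W_i = init_mat(hidden, nc, init), b_i = numeric(hidden),
      W_f = init_mat(hidden, nc, init), b_f = numeric(hidden),
      W_o = init_mat(hidden, nc, init), b_o = numeric(hidden)
    )
  })
  structure(c(p, list(hidden = as.integer(hidden), input_dim = as.integer(input_dim))),
            class = "lstm_params")
}

#' LSTM state
#'
#' @param h Hidden vector.
#' @param c Cell vector.
#' @return An `lstm_state` list.
#' @export
lstm_state <- function(h, c = NULL) {
  if (length(h) == 1L && is.numeric(h) && h == floor(h) && is.null(c) && h > 1) {
    # lstm_state(hidden_size) shorthand for the zero state
    h <- numeric(h)
  }
  if (is.null(c)) c <- numeric(length(h))
  if (length(h) != length(c)) stop_validation("h and c must have equal length")
  structure(list(h = as.numeric(h), c = as.numeric(c)), class = "lstm_state")
}

#' One LSTM step
#'
#' Computes, with `A = [h_{t-1}, x_t]`:
#' `z = tanh(W_z A + b_z)`; `i, f, o` the sigmoid input/forget/output gates;
#' `c_t = f * c_{t-1} + i * z`; `h_t = o * tanh(c_t)`.
#'
#' @param x_t Input vector.
#' @param state An `lstm_state`.
#' @param params An `lstm_params`.
#' @return The next `lstm_state`.
#' @export
lstm_step <- function(x_t, state, params) {
  A <- c(state$h, x_t)
  if (length(A) != ncol(params$W_z)) {
    stop_validation("lstm_step: state/input dimensions do not match parameters")
  }
  z <- tanh(drop(params$W_z %*% A) + params$b_z)
  i <- activation_fn("sigmoid")(drop(params$W_i %*% A) + params$b_i)
  f <- activation_fn("sigmoid")(drop(params$W_f %*% A) + params$b_f)
  o <- activation_fn("sigmoid")(drop(params$W_o %*% A) + params$b_o)
  cc <- f * state$c + i * z
  lstm_state(o * tanh(cc), cc)
}

#' Run an LSTM over a sequence
#'
#' @param X Matrix `[T x d]`, one row per timestep.
#' @param params An `lstm_params`.
#' @param init Initial `lstm_state` (zero state if NULL).
#' @return List with `outputs` (`[T x hidden]` of `h_t`), `cells`
#'   (`[T x hidden]` of `c_t`) and `state` (final `lstm_state`).
#' @export
lstm_sequence <- function(X, params, init = NULL) {
  check_matrix(X, "X")
  if (nrow(X) < 1L) stop_validation("sequence must have at least one timestep")
  st <- init %||% lstm_state(numeric(params$hidden))
  H <- matrix(0, nrow(X), params$hidden)
  C <- matrix(0, nrow(X), params$hidden)
  for (t in seq_len(nrow(X))) {
    st <- lstm_step(X[t, ], st, params)
    H[t, ] <- st$h
    C[t, ] <- st$c
  }
  list(outputs = H, cells = C, state = st)
}

#' GRU parameter bundle
#'
#' Three weight matrices of shape `[hidden x (hidden + input_dim)]` on the
#' concatenated `[h_{t-1}, x_t]` (the separate input-weight matrices of the
#' textbook notation are absorbed into the concatenated form).
#'
#' @inheritParams lstm_params
#' @return A `gru_params` list.
#' @export
gru_params <- function(input_dim, hidden, init = c("uniform", "zero"), seed = 1L) {
  init <- match.arg(init)
  nc <- hidden + input_dim
  withr::with_seed(as.integer(seed), {
    p <- list(W_z = init_mat(hidden, nc, init),
              W_r = init_mat(hidden, nc, init),
              W = init_mat(hidden, nc, init))
  })
  structure(c(p, list(hidden = as.integer(hidden), input_dim = as.integer(input_dim))),
            class = "gru_params")
}

#' One GRU step
#'
#' `z = sigmoid(W_z [h, x])`; `r = sigmoid(W_r [h, x])`;
#' `h~ = tanh(W [r * h, x])`; `h_t = (1 - z) * h_{t-1} + z * h~`.
#'
#' @param x_t Input vector.
#' @param h_prev Previous hidden vector.
#' @param params A `gru_params`.
#' @return The next hidden vector.
#' @export
gru_step <- function(x_t, h_prev, params) {
  A <- c(h_prev, x_t)
  if (length(A) != ncol(params$W_z)) {
    stop_validation("gru_step: state/input dimensions do not match parameters")
  }
  sg <- activation_fn("sigmoid")
  z <- sg(drop(params$W_z %*% A))
  r <- sg(drop(params$W_r %*% A))
  htil <- tanh(drop(params$W %*% c(r * h_prev, x_t)))
  (1 - z) * h_prev + z * htil
}

#' Bidirectional GRU parameter bundle
#'
#' @inheritParams lstm_params
#' @return A `bigru_params` list with `forward` and `backward` `gru_params`.
#' @export
bigru_params <- function(input_dim, hidden, init = c("uniform", "zero"), seed = 1L) {
  init <- match.arg(init)
  structure(
    list(forward = gru_params(input_dim, hidden, init, derive_seed(seed, "fwd")),
         backward = gru_params(input_dim, hidden, init, derive_seed(seed, "bwd")),
         hidden = as.integer(hidden), input_dim = as.integer(input_dim)),
    class = "bigru_params"
  )
}

#' Run a bidirectional GRU over a sequence
#'
#' The forward GRU reads `X` left to right; the backward GRU reads it right
#' to left. Output row `t` is the concatenation of the two directional
#' hidden states at position `t`.
#'
#' @param X Matrix `[T x d]`.
#' @param params A `bigru_params`.
#' @return Matrix `[T x 2*hidden]`.
#' @export
bigru_sequence <- function(X, params) {
  check_matrix(X, "X")
  T_ <- nrow(X)
  if (T_ < 1L) stop_validation("sequence must have at least one timestep")
  H <- params$hidden
  Fo <- matrix(0, T_, H)
  h <- numeric(H)
  for (t in seq_len(T_)) {
    h <- gru_step(X[t, ], h, params$forward)
    Fo[t, ] <- h
  }
  Bo <- matrix(0, T_, H)
  h <- numeric(H)
  for (t in rev(seq_len(T_))) {
    h <- gru_step(X[t, ], h, params$backward)
    Bo[t, ] <- h
  }
  cbind(Fo, Bo)
}

#' Convolution filter bank for text
#'
#' For each width `h` in `widths`, holds `n_filters` kernels of shape
#' `h * d` (stored flattened, position-major) plus biases and a shared
#' activation name.
#'
#' @param widths Integer vector of filter widths.
#' @param n_filters Filters per width.
#' @param d Input (embedding) dimension.
#' @param activation Activation name (see [apply_activation()]).
#' @param init `"zero"` or `"uniform"`.
#' @param seed Seed for initialization.
#' @return A `conv_bank` list.
#' @export
conv_bank <- function(widths, n_filters, d, activation = "relu",
                      init = c("uniform", "zero"), seed = 1L) {
  init <- match.arg(init)
  if (any(widths < 1L)) stop_validation("filter widths must be positive")
  filters <- withr::with_seed(as.integer(seed), {
    stats::setNames(lapply(widths, function(h) {
      list(W = init_mat(n_filters, h * d, init), b = numeric(n_filters))
    }), as.character(widths))
  })
  structure(list(widths = as.integer(widths), n_filters = as.integer(n_filters),
                 d = as.integer(d), activation = activation, filters = filters),
            class = "conv_bank")
}

#' 1-D text convolution (valid, stride 1)
#'
#' For each filter of width `h`, `t_i = f(w . x_{i:i+h-1} + b)` over all
#' `n - h + 1` windows of the `[n x d]` input.
#'
#' @param X Matrix `[n x d]` (one embedded token per row).
#' @param bank A `conv_bank`.
#' @return Named list (by width) of feature maps, each `[(n - h + 1) x
#'   n_filters]`.
#' @export
conv1d_text <- function(X, bank) {
  check_matrix(X, "X")
  n <- nrow(X)
  if (n < max(bank$widths)) {
    stop_validation(sprintf("sequence length %d shorter than max filter width %d",
                            n, max(bank$widths)))
  }
  if (ncol(X) != bank$d) stop_validation("input dimension does not match bank")
  f <- activation_fn(bank$activation)
  out <- lapply(seq_along(bank$widths), function(wi) {
    h <- bank$widths[wi]
    flt <- bank$filters[[wi]]
    map <- matrix(0, n - h + 1L, bank$n_filters)
    for (t in seq_len(n - h + 1L)) {
      win <- as.vector(t(X[t:(t + h - 1L), , drop = FALSE]))
      map[t, ] <- drop(flt$W %*% win) + flt$b
    }
    f(map)
  })
  stats::setNames(out, as.character(bank$widths))
}

#' Pool feature maps over time
#'
#' @param maps A feature map matrix (`[time x filters]`) or a list of them
#'   (as returned by [conv1d_text()]).
#' @param mode `"max"` or `"avg"`.
#' @return Numeric vector, one value per filter (concatenated across maps).
#' @export
pool_time <- function(maps, mode = c("max", "avg")) {
  mode <- match.arg(mode)
  if (is.matrix(maps)) maps <- list(maps)
  unlist(lapply(maps, function(m) {
    if (!nrow(m)) stop_validation("cannot pool an empty feature map")
    if (mode == "max") apply(m, 2L, max) else colMeans(m)
  }), use.names = FALSE)
}

#' Hybrid (additive) attention parameters
#'
#' @param m Input row dimension (for the quad-channel model,
#'   `2 * hidden`: the concatenated hidden and cell states).
#' @param attn_dim Projection dimension (rows of `W_r`, length of `v_a`).
#' @param init `"zero"` or `"uniform"`.
#' @param seed Seed.
#' @return A `hybrid_attention_params` list with `W_r`, `v_a`, `b`.
#' @export
hybrid_attention_params <- function(m, attn_dim, init = c("uniform", "zero"), seed = 1L) {
  init <- match.arg(init)
  withr::with_seed(as.integer(seed), {
    p <- list(W_r = init_mat(attn_dim, m, init),
              v_a = if (init == "zero") numeric(attn_dim) else
                stats::runif(attn_dim, -0.1, 0.1),
              b = numeric(attn_dim))
  })
  structure(c(p, list(m = as.integer(m), attn_dim = as.integer(attn_dim))),
            class = "hybrid_attention_params")
}

#' Hybrid attention over a sequence of hidden states
#'
#' Scores each row by `e_i = v_a' tanh(W_r h_i + b)`, normalizes the scores
#' with a softmax over positions, and returns the weighted sum of the rows.
#'
#' @param H Matrix `[T x m]` of per-position vectors (for the quad-channel
#'   model, the concatenation of the LSTM hidden and cell states).
#' @param params A `hybrid_attention_params`.
#' @return Context vector of length `m`, with the attention weights in the
#'   `"weights"` attribute.
#' @export
hybrid_attention <- function(H, params) {
  check_matrix(H, "H")
  if (nrow(H) < 1L) stop_validation("attention needs at least one position")
  if (ncol(H) != ncol(params$W_r)) stop_validation("H columns must match W_r columns")
  U <- tanh(H %*% t(params$W_r) + matrix(params$b, nrow(H), params$attn_dim, byrow = TRUE))
  e <- drop(U %*% params$v_a)
  w <- softmax_vec(e)
  structure(drop(crossprod(H, w)), weights = w)
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d)) V`, the softmax taken over
#' each row.
#'
#' @param Q,K,V Matrices; `Q` is `[n_q x d]`, `K` `[n_k x d]`, `V`
#'   `[n_k x d_v]`.
#' @return Matrix `[n_q x d_v]`, attention weights in the `"weights"`
#'   attribute.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  check_matrix(Q, "Q"); check_matrix(K, "K"); check_matrix(V, "V")
  d <- ncol(K)
  if (d == 0L) stop_validation("key dimension must be positive")
  if (ncol(Q) != d) stop_validation("Q and K must share the key dimension")
  if (nrow(K) != nrow(V)) stop_validation("K and V must have the same number of rows")
  A <- softmax_rows(Q %*% t(K) / sqrt(d))
  structure(A %*% V, weights = A)
}

#' Multihead attention parameters
#'
#' Per-head query/key/value projections of shape `[d_head x d_model]`
#' (`d_head = d_model / n_heads`) plus an output projection `W_O`
#' `[d_model x d_model]` merging the concatenated heads.
#'
#' @param n_heads Number of heads; must divide `d_model`.
#' @param d_model Model (input/output) dimension.
#' @param init `"identity"` builds the single-head identity configuration
#'   (requires `n_heads = 1`), otherwise Glorot-uniform.
#' @param seed Seed.
#' @return A `multihead_params` list.
#' @export
multihead_params <- function(n_heads, d_model, init = c("uniform", "identity"), seed = 1L) {
  init <- match.arg(init)
  if (d_model %% n_heads != 0L) {
    stop_validation("model dimension must be divisible by the number of heads")
  }
  dh <- d_model %/% n_heads
  mk <- function(s) {
    if (init == "identity") {
      if (n_heads != 1L) stop_validation("identity initialization requires a single head")
      diag(d_model)
    } else {
      withr::with_seed(s, init_mat(dh, d_model, "uniform"))
    }
  }
  heads <- lapply(seq_len(n_heads), function(i) {
    list(W_q = mk(derive_seed(seed, paste0("q", i))),
         W_k = mk(derive_seed(seed, paste0("k", i))),
         W_v = mk(derive_seed(seed, paste0("v", i))))
  })
  W_o <- if (init == "identity") diag(d_model) else
    withr::with_seed(derive_seed(seed, "o"), init_mat(d_model, d_model, "uniform"))
  structure(list(n_heads = as.integer(n_heads), d_model = as.integer(d_model),
                 d_head = as.integer(dh), heads = heads, W_o = W_o),
            class = "multihead_params")
}

#' Multihead (self-)attention
#'
#' Each head projects `Q`, `K`, `V` with its own matrices, applies
#' [scaled_dot_attention()] at the per-head key dimension, and the
#' concatenated head outputs are merged by the output projection `W_O`.
#' Passing the same matrix as `Q`, `K` and `V` gives self-attention.
#'
#' @param Q,K,V Matrices `[n x d_model]`.
#' @param params A `multihead_params`.
#' @return Matrix `[n x d_model]`.
#' @export
multihead_attention <- function(Q, K, V, params) {
  check_matrix(Q, "Q"); check_matrix(K, "K"); check_matrix(V, "V")
  if (ncol(Q) != params$d_model) stop_validation("input dimension must equal d_model")
  heads <- lapply(params$heads, function(hp) {
    scaled_dot_attention(Q %*% t(hp$W_q), K %*% t(hp$W_k), V %*% t(hp$W_v))
  })
  concat <- do.call(cbind, heads)
  concat %*% t(params$W_o)
}

#' Dense layer parameters
#'
#' @param input_dim Input dimension.
#' @param n_classes Output dimension (number of classes).
#' @param init `"zero"` or `"uniform"`.
#' @param seed Seed.
#' @return A `dense_params` list with `W` `[n_classes x input_dim]` and `b`.
#' @export
dense_params <- function(input_dim, n_classes, init = c("uniform", "zero"), seed = 1L) {
  init <- match.arg(init)
  withr::with_seed(as.integer(seed), {
    W <- init_mat(n_classes, input_dim, init)
  })
  structure(list(W = W, b = numeric(n_classes),
                 input_dim = as.integer(input_dim), n_classes = as.integer(n_classes)),
            class = "dense_params")
}

#' Fully connected layer followed by softmax
#'
#' @param h Input vector.
#' @param params A `dense_params`.
#' @return Probability vector (positive, sums to 1).
#' @export
dense_softmax <- function(h, params) {
  if (length(h) != ncol(params$W)) stop_validation("dense_softmax: dimension mismatch")
  softmax_vec(drop(params$W %*% h) + params$b)
}

#' Cross-entropy loss
#'
#' For two classes this is the binary cross entropy
#' `L = -(1/N) sum_i [y_i log p_i + (1 - y_i) log(1 - p_i)]` with `p_i` the
#' predicted probability of the positive class (class 1). For more than two
#' mutually exclusive classes it generalizes to the categorical form
#' `L = -(1/N) sum_i log p_{i, y_i}`. Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param p Either a probability matrix `[N x C]` or, for the binary case, a
#'   numeric vector of positive-class probabilities.
#' @param y Integer labels in `[0, C)`.
#' @return Scalar mean loss.
#' @export
cross_entropy_loss <- function(p, y) {
  eps <- 1e-7
  if (!is.matrix(p)) {
    if (any(y != 0L & y != 1L)) stop_validation("binary labels must be 0 or 1")
    if (length(p) != length(y)) stop_validation("p and y lengths differ")
    pc <- pmin(pmax(p, eps), 1 - eps)
    return(-mean(y * log(pc) + (1 - y) * log(1 - pc)))
  }
  C <- ncol(p)
  if (any(y < 0L | y >= C)) stop_validation(sprintf("labels must lie in [0, %d)", C))
  if (nrow(p) != length(y)) stop_validation("p rows and y length differ")
  pc <- pmin(pmax(p, eps), 1 - eps)
  if (C == 2L) {
    pos <- pc[, 2L]
    -mean(y * log(pos) + (1 - y) * log(1 - pos))
  } else {
    -mean(log(pc[cbind(seq_along(y), y + 1L)]))
  }
}
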