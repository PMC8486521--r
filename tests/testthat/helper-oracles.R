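# Brute-force oracles, written independently of the vectorized layer code:
# plain scalar loops and direct formula transcriptions.

oracle_lstm_step <- function(x, h_prev, c_prev, p) {
  H <- p$hidden
  a <- c(h_prev, x)
  h_new <- numeric(H); c_new <- numeric(H)
  for (j in seq_len(H)) {
    z <- tanh(sum(p$W_z[j, ] * a) + p$b_z[j])
    i <- 1 / (1 + exp(-(sum(p$W_i[j, ] * a) + p$b_i[j])))
    f <- 1 / (1 + exp(-(sum(p$W_f[j, ] * a) + p$b_f[j])))
    o <- 1 / (1 + exp(-(sum(p$W_o[j, ] * a) + p$b_o[j])))
    c_new[j] <- f * c_prev[j] + i * z
    h_new[j] <- o * tanh(c_new[j])
  }
  list(h = h_new, c = c_new)
}

oracle_gru_step <- function(x, h_prev, p) {
  H <- p$hidden
  a <- c(h_prev, x)
  h_new <- numeric(H)
  z <- numeric(H); r <- numeric(H)
  for (j in seq_len(H)) {
    z[j] <- 1 / (1 + exp(-sum(p$W_z[j, ] * a)))
    r[j] <- 1 / (1 + exp(-sum(p$W_r[j, ] * a)))
  }
  a2 <- c(r * h_prev, x)
  for (j in seq_len(H)) {
    htil <- tanh(sum(p$W[j, ] * a2))
    h_new[j] <- (1 - z[j]) * h_prev[j] + z[j] * htil
  }
  h_new
}

oracle_conv1d <- function(X, bank) {
  f <- switch(bank$activation,
              relu = function(v) pmax(v, 0),
              linear = identity,
              sigmoid = function(v) 1 / (1 + exp(-v)),
              tanh = tanh)
  out <- list()
  for (wi in seq_along(bank$widths)) {
    h <- bank$widths[wi]
    flt <- bank$filters[[wi]]
    n <- nrow(X)
    map <- matrix(0, n - h + 1, bank$n_filters)
    for (t in seq_len(n - h + 1)) {
      win <- c()
      for (pos in t:(t + h - 1)) win <- c(win, X[pos, ])
      for (k in seq_len(bank$n_filters)) {
        map[t, k] <- f(sum(flt$W[k, ] * win) + flt$b[k])
      }
    }
    out[[as.character(h)]] <- map
  }
  out
}

oracle_hybrid_attention <- function(H, p) {
  T_ <- nrow(H)
  e <- numeric(T_)
  for (t in seq_len(T_)) {
    e[t] <- sum(p$v_a * tanh(drop(p$W_r %*% H[t, ]) + p$b))
  }
  w <- exp(e - max(e)); w <- w / sum(w)
  ctx <- numeric(ncol(H))
  for (t in seq_len(T_)) ctx <- ctx + w[t] * H[t, ]
  ctx
}

oracle_scaled_dot <- function(Q, K, V) {
  d <- ncol(K)
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

oracle_multihead <- function(Q, K, V, p) {
  pieces <- list()
  for (hp in p$heads) {
    pieces[[length(pieces) + 1L]] <-
      oracle_scaled_dot(Q %*% t(hp$W_q), K %*% t(hp$W_k), V %*% t(hp$W_v))
  }
  do.call(cbind, pieces) %*% t(p$W_o)
}

rand_mat <- function(nr, nc) matrix(stats::rnorm(nr * nc), nr, nc)

`%||%` <- function(a, b) if (is.null(a)) b else a

softmax_rows_ref <- function(z) {
  t(apply(z, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
}
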