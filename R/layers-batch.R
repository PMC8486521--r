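# Internal batched forward/backward passes used by the training engine.
# Layout conventions:
#   - encoded indices: integer matrix [B x T], 0-based
#   - embedded sequences: array [B, T, d]
#   - recurrent states: matrices [B x hidden]
# Every *_bwd returns the parameter gradients (mirroring the parameter list
# names) plus the gradient w.r.t. its input.

slice_t <- function(A, t) {
  d <- dim(A)
  matrix(A[, t, ], d[1], d[3])
}

sigm <- function(z) 1 / (1 + exp(-z))

## ---- embedding ----

bemb_fwd <- function(idx, E) {
  B <- nrow(idx); T_ <- ncol(idx); d <- ncol(E)
  if (any(idx < 0L) || any(idx >= nrow(E))) {
    stop_validation("encoded index out of embedding range")
  }
  flat <- E[as.vector(idx) + 1L, , drop = FALSE]
  array(as.vector(flat), dim = c(B, T_, d))
}

bemb_bwd <- function(dA, idx, V) {
  B <- dim(dA)[1]; T_ <- dim(dA)[2]; d <- dim(dA)[3]
  flat <- matrix(as.vector(dA), B * T_, d)
  acc <- rowsum(flat, group = as.vector(idx) + 1L)
  dE <- matrix(0, V, d)
  dE[as.integer(rownames(acc)), ] <- acc
  dE
}

## ---- convolution + global pooling ----

conv_window <- function(A, t, h) {
  d <- dim(A)
  sub <- A[, t:(t + h - 1L), , drop = FALSE]
  matrix(aperm(sub, c(1L, 3L, 2L)), d[1], h * d[3])  # position-major, d inner
}

bconv_fwd <- function(A, bank) {
  B <- dim(A)[1]; T_ <- dim(A)[2]
  f <- activation_fn(bank$activation)
  maps <- vector("list", length(bank$widths))
  pre <- vector("list", length(bank$widths))
  for (wi in seq_along(bank$widths)) {
    h <- bank$widths[wi]
    flt <- bank$filters[[wi]]
    Tm <- T_ - h + 1L
    Z <- array(0, c(B, Tm, bank$n_filters))
    for (t in seq_len(Tm)) {
      Z[, t, ] <- conv_window(A, t, h) %*% t(flt$W) +
        matrix(flt$b, B, bank$n_filters, byrow = TRUE)
    }
    pre[[wi]] <- Z
    maps[[wi]] <- f(Z)
  }
  list(maps = maps, cache = list(pre = pre, A = A))
}

bconv_bwd <- function(dmaps, cache, bank) {
  A <- cache$A
  B <- dim(A)[1]; T_ <- dim(A)[2]; d <- dim(A)[3]
  gfun <- activation_grad(bank$activation)
  dA <- array(0, dim(A))
  grads <- stats::setNames(vector("list", length(bank$widths)), names(bank$filters))
  for (wi in seq_along(bank$widths)) {
    h <- bank$widths[wi]
    flt <- bank$filters[[wi]]
    Z <- cache$pre[[wi]]
    Tm <- T_ - h + 1L
    gW <- matrix(0, bank$n_filters, h * d)
    gb <- numeric(bank$n_filters)
    for (t in seq_len(Tm)) {
      Zt <- matrix(Z[, t, ], B, bank$n_filters)
      dZ <- matrix(dmaps[[wi]][, t, ], B, bank$n_filters) * gfun(Zt, activation_fn(bank$activation)(Zt))
      win <- conv_window(A, t, h)
      gW <- gW + crossprod(dZ, win)
      gb <- gb + colSums(dZ)
      dwin <- dZ %*% flt$W
      # scatter window gradient back to positions t..t+h-1
      dsub <- aperm(array(as.vector(dwin), c(B, d, h)), c(1L, 3L, 2L))
      r <- t:(t + h - 1L)
      dA[, r, ] <- dA[, r, , drop = FALSE] + dsub
    }
    grads[[wi]] <- list(W = gW, b = gb)
  }
  list(filters = grads, dA = dA)
}

# Global pooling over the time axis of a [B, Tm, F] map.
bpool_max_fwd <- function(M) {
  B <- dim(M)[1]; Tm <- dim(M)[2]; F_ <- dim(M)[3]
  cur <- matrix(M[, 1L, ], B, F_)
  arg <- matrix(1L, B, F_)
  if (Tm > 1L) for (t in 2:Tm) {
    mt <- matrix(M[, t, ], B, F_)
    upd <- mt > cur
    cur[upd] <- mt[upd]
    arg[upd] <- t
  }
  list(out = cur, arg = arg)
}

bpool_max_bwd <- function(dout, arg, dims) {
  dM <- array(0, dims)
  for (t in seq_len(dims[2])) {
    mask <- arg == t
    if (any(mask)) {
      sl <- matrix(0, dims[1], dims[3])
      sl[mask] <- dout[mask]
      dM[, t, ] <- sl
    }
  }
  dM
}

bpool_avg_fwd <- function(M) {
  B <- dim(M)[1]; Tm <- dim(M)[2]; F_ <- dim(M)[3]
  acc <- matrix(0, B, F_)
  for (t in seq_len(Tm)) acc <- acc + matrix(M[, t, ], B, F_)
  acc / Tm
}

bpool_avg_bwd <- function(dout, dims) {
  dM <- array(0, dims)
  per <- dout / dims[2]
  for (t in seq_len(dims[2])) dM[, t, ] <- per
  dM
}

## ---- LSTM ----

blstm_fwd <- function(A, params) {
  B <- dim(A)[1]; T_ <- dim(A)[2]
  H <- params$hidden
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- vector("list", T_)
  Hs <- vector("list", T_); Cs <- vector("list", T_)
  bz <- matrix(params$b_z, B, H, byrow = TRUE)
  bi <- matrix(params$b_i, B, H, byrow = TRUE)
  bf <- matrix(params$b_f, B, H, byrow = TRUE)
  bo <- matrix(params$b_o, B, H, byrow = TRUE)
  for (t in seq_len(T_)) {
    AA <- cbind(h, slice_t(A, t))
    z <- tanh(AA %*% t(params$W_z) + bz)
    i <- sigm(AA %*% t(params$W_i) + bi)
    f <- sigm(AA %*% t(params$W_f) + bf)
    o <- sigm(AA %*% t(params$W_o) + bo)
    c_prev <- cc
    cc <- f * c_prev + i * z
    hc <- tanh(cc)
    h <- o * hc
    steps[[t]] <- list(AA = AA, z = z, i = i, f = f, o = o,
                       c_prev = c_prev, hc = hc)
    Hs[[t]] <- h; Cs[[t]] <- cc
  }
  list(Hs = Hs, Cs = Cs, cache = steps)
}

blstm_bwd <- function(dHs, dCs, cache, params, input_dims) {
  T_ <- length(cache)
  B <- nrow(cache[[1]]$AA)
  H <- params$hidden
  gz <- matrix(0, nrow(params$W_z), ncol(params$W_z)); gbz <- numeric(H)
  gi <- gz; gbi <- gbz; gf <- gz; gbf <- gbz; go <- gz; gbo <- gbz
  dA <- array(0, input_dims)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    st <- cache[[t]]
    dh <- dh_next + (if (is.null(dHs[[t]])) 0 else dHs[[t]])
    dc <- dc_next + (if (is.null(dCs[[t]])) 0 else dCs[[t]])
    do_ <- dh * st$hc
    dct <- dc + dh * st$o * (1 - st$hc^2)
    df <- dct * st$c_prev
    di <- dct * st$z
    dz <- dct * st$i
    dc_next <- dct * st$f
    dZz <- dz * (1 - st$z^2)
    dZi <- di * st$i * (1 - st$i)
    dZf <- df * st$f * (1 - st$f)
    dZo <- do_ * st$o * (1 - st$o)
    gz <- gz + crossprod(dZz, st$AA); gbz <- gbz + colSums(dZz)
    gi <- gi + crossprod(dZi, st$AA); gbi <- gbi + colSums(dZi)
    gf <- gf + crossprod(dZf, st$AA); gbf <- gbf + colSums(dZf)
    go <- go + crossprod(dZo, st$AA); gbo <- gbo + colSums(dZo)
    dAA <- dZz %*% params$W_z + dZi %*% params$W_i +
      dZf %*% params$W_f + dZo %*% params$W_o
    dh_next <- dAA[, seq_len(H), drop = FALSE]
    dA[, t, ] <- dAA[, H + seq_len(ncol(dAA) - H), drop = FALSE]
  }
  list(grads = list(W_z = gz, b_z = gbz, W_i = gi, b_i = gbi,
                    W_f = gf, b_f = gbf, W_o = go, b_o = gbo),
       dA = dA)
}

## ---- GRU / BiGRU ----

bgru_fwd <- function(A, params, reverse = FALSE) {
  B <- dim(A)[1]; T_ <- dim(A)[2]
  H <- params$hidden
  h <- matrix(0, B, H)
  order_t <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  steps <- vector("list", T_)
  Hs <- vector("list", T_)
  for (t in order_t) {
    Xt <- slice_t(A, t)
    AA <- cbind(h, Xt)
    z <- sigm(AA %*% t(params$W_z))
    r <- sigm(AA %*% t(params$W_r))
    h_prev <- h
    A2 <- cbind(r * h_prev, Xt)
    htil <- tanh(A2 %*% t(params$W))
    h <- (1 - z) * h_prev + z * htil
    steps[[t]] <- list(AA = AA, A2 = A2, z = z, r = r, htil = htil, h_prev = h_prev)
    Hs[[t]] <- h
  }
  list(Hs = Hs, cache = steps, reverse = reverse)
}

bgru_bwd <- function(dHs, fwd, params, input_dims) {
  cache <- fwd$cache
  T_ <- length(cache)
  B <- nrow(cache[[if (fwd$reverse) T_ else 1L]]$AA)
  H <- params$hidden
  gWz <- matrix(0, nrow(params$W_z), ncol(params$W_z))
  gWr <- gWz; gW <- gWz
  dA <- array(0, input_dims)
  dh_next <- matrix(0, B, H)
  order_t <- if (fwd$reverse) seq_len(T_) else rev(seq_len(T_))
  for (t in order_t) {
    st <- cache[[t]]
    dh <- dh_next + (if (is.null(dHs[[t]])) 0 else dHs[[t]])
    dz <- dh * (st$htil - st$h_prev)
    dhtil <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    dZh <- dhtil * (1 - st$htil^2)
    gW <- gW + crossprod(dZh, st$A2)
    dA2 <- dZh %*% params$W
    dr <- dA2[, seq_len(H), drop = FALSE] * st$h_prev
    dh_prev <- dh_prev + dA2[, seq_len(H), drop = FALSE] * st$r
    dXt <- dA2[, H + seq_len(ncol(dA2) - H), drop = FALSE]
    dZz <- dz * st$z * (1 - st$z)
    dZr <- dr * st$r * (1 - st$r)
    gWz <- gWz + crossprod(dZz, st$AA)
    gWr <- gWr + crossprod(dZr, st$AA)
    dAA <- dZz %*% params$W_z + dZr %*% params$W_r
    dh_prev <- dh_prev + dAA[, seq_len(H), drop = FALSE]
    dXt <- dXt + dAA[, H + seq_len(ncol(dAA) - H), drop = FALSE]
    dh_next <- dh_prev
    dA[, t, ] <- dA[, t, ] + dXt
  }
  list(grads = list(W_z = gWz, W_r = gWr, W = gW), dA = dA)
}

bbigru_fwd <- function(A, params) {
  fwd <- bgru_fwd(A, params$forward, reverse = FALSE)
  bwd <- bgru_fwd(A, params$backward, reverse = TRUE)
  B <- dim(A)[1]; T_ <- dim(A)[2]; H <- params$hidden
  Y <- array(0, c(B, T_, 2L * H))
  for (t in seq_len(T_)) {
    Y[, t, seq_len(H)] <- fwd$Hs[[t]]
    Y[, t, H + seq_len(H)] <- bwd$Hs[[t]]
  }
  list(Y = Y, fwd = fwd, bwd = bwd)
}

bbigru_bwd <- function(dY, st, params, input_dims) {
  T_ <- dim(dY)[2]; H <- params$hidden; B <- dim(dY)[1]
  dF <- lapply(seq_len(T_), function(t) matrix(dY[, t, seq_len(H)], B, H))
  dB <- lapply(seq_len(T_), function(t) matrix(dY[, t, H + seq_len(H)], B, H))
  rf <- bgru_bwd(dF, st$fwd, params$forward, input_dims)
  rb <- bgru_bwd(dB, st$bwd, params$backward, input_dims)
  list(grads = list(forward = rf$grads, backward = rb$grads),
       dA = rf$dA + rb$dA)
}

## ---- hybrid attention ----

bhattn_fwd <- function(Hcat, params) {
  B <- dim(Hcat)[1]; T_ <- dim(Hcat)[2]; m <- dim(Hcat)[3]
  a <- params$attn_dim
  U <- vector("list", T_)
  e <- matrix(0, B, T_)
  bmat <- matrix(params$b, B, a, byrow = TRUE)
  for (t in seq_len(T_)) {
    Ut <- tanh(slice_t(Hcat, t) %*% t(params$W_r) + bmat)
    U[[t]] <- Ut
    e[, t] <- Ut %*% params$v_a
  }
  w <- softmax_rows(e)
  ctx <- matrix(0, B, m)
  for (t in seq_len(T_)) ctx <- ctx + w[, t] * slice_t(Hcat, t)
  list(out = ctx, cache = list(U = U, w = w, Hcat = Hcat))
}

bhattn_bwd <- function(dctx, cache, params) {
  Hcat <- cache$Hcat; w <- cache$w; U <- cache$U
  B <- dim(Hcat)[1]; T_ <- dim(Hcat)[2]; m <- dim(Hcat)[3]
  dw <- matrix(0, B, T_)
  dH <- array(0, dim(Hcat))
  for (t in seq_len(T_)) {
    Ht <- slice_t(Hcat, t)
    dw[, t] <- rowSums(dctx * Ht)
    dH[, t, ] <- dctx * w[, t]
  }
  de <- w * (dw - rowSums(w * dw))
  gWr <- matrix(0, params$attn_dim, m)
  gva <- numeric(params$attn_dim)
  gb <- numeric(params$attn_dim)
  for (t in seq_len(T_)) {
    Ut <- U[[t]]
    gva <- gva + drop(crossprod(Ut, de[, t]))
    dU <- tcrossprod(de[, t], params$v_a) * (1 - Ut^2)
    gWr <- gWr + crossprod(dU, slice_t(Hcat, t))
    gb <- gb + colSums(dU)
    dH[, t, ] <- dH[, t, ] + dU %*% params$W_r
  }
  list(grads = list(W_r = gWr, v_a = gva, b = gb), dA = dH)
}

## ---- multihead self-attention ----

bmha_fwd <- function(Y, params) {
  B <- dim(Y)[1]; T_ <- dim(Y)[2]; m <- dim(Y)[3]
  dh <- params$d_head
  Yflat <- matrix(as.vector(Y), B * T_, m)
  head_out <- vector("list", params$n_heads)
  head_cache <- vector("list", params$n_heads)
  for (hi in seq_len(params$n_heads)) {
    hp <- params$heads[[hi]]
    Qf <- Yflat %*% t(hp$W_q)
    Kf <- Yflat %*% t(hp$W_k)
    Vf <- Yflat %*% t(hp$W_v)
    Qa <- array(as.vector(Qf), c(B, T_, dh))
    Ka <- array(as.vector(Kf), c(B, T_, dh))
    Va <- array(as.vector(Vf), c(B, T_, dh))
    Oa <- array(0, c(B, T_, dh))
    Aw <- vector("list", B)
    for (b in seq_len(B)) {
      Qb <- matrix(Qa[b, , ], T_, dh)
      Kb <- matrix(Ka[b, , ], T_, dh)
      Vb <- matrix(Va[b, , ], T_, dh)
      S <- Qb %*% t(Kb) / sqrt(dh)
      Ab <- softmax_rows(S)
      Oa[b, , ] <- Ab %*% Vb
      Aw[[b]] <- Ab
    }
    head_out[[hi]] <- Oa
    head_cache[[hi]] <- list(Q = Qa, K = Ka, V = Va, Aw = Aw)
  }
  concat <- array(0, c(B, T_, m))
  for (hi in seq_len(params$n_heads)) {
    concat[, , (hi - 1L) * dh + seq_len(dh)] <- head_out[[hi]]
  }
  cflat <- matrix(as.vector(concat), B * T_, m)
  out_flat <- cflat %*% t(params$W_o)
  list(out = array(as.vector(out_flat), c(B, T_, m)),
       cache = list(Yflat = Yflat, cflat = cflat, heads = head_cache,
                    dims = c(B, T_, m)))
}

bmha_bwd <- function(dout, cache, params) {
  dims <- cache$dims
  B <- dims[1]; T_ <- dims[2]; m <- dims[3]
  dh <- params$d_head
  dflat <- matrix(as.vector(dout), B * T_, m)
  gWo <- crossprod(dflat, cache$cflat)
  dconcat_flat <- dflat %*% params$W_o
  dconcat <- array(as.vector(dconcat_flat), c(B, T_, m))
  dY_flat <- matrix(0, B * T_, m)
  head_grads <- vector("list", params$n_heads)
  for (hi in seq_len(params$n_heads)) {
    hc <- cache$heads[[hi]]
    hp <- params$heads[[hi]]
    dO <- dconcat[, , (hi - 1L) * dh + seq_len(dh), drop = FALSE]
    dQ <- array(0, c(B, T_, dh)); dK <- dQ; dV <- dQ
    for (b in seq_len(B)) {
      dOb <- matrix(dO[b, , , drop = TRUE], T_, dh)
      Ab <- hc$Aw[[b]]
      Vb <- matrix(hc$V[b, , ], T_, dh)
      Qb <- matrix(hc$Q[b, , ], T_, dh)
      Kb <- matrix(hc$K[b, , ], T_, dh)
      dA <- dOb %*% t(Vb)
      dV[b, , ] <- crossprod(Ab, dOb)
      dS <- Ab * (dA - rowSums(Ab * dA))
      dQ[b, , ] <- dS %*% Kb / sqrt(dh)
      dK[b, , ] <- crossprod(dS, Qb) / sqrt(dh)
    }
    dQf <- matrix(as.vector(dQ), B * T_, dh)
    dKf <- matrix(as.vector(dK), B * T_, dh)
    dVf <- matrix(as.vector(dV), B * T_, dh)
    head_grads[[hi]] <- list(W_q = crossprod(dQf, cache$Yflat),
                             W_k = crossprod(dKf, cache$Yflat),
                             W_v = crossprod(dVf, cache$Yflat))
    dY_flat <- dY_flat + dQf %*% hp$W_q + dKf %*% hp$W_k + dVf %*% hp$W_v
  }
  list(grads = list(heads = head_grads, W_o = gWo),
       dA = array(as.vector(dY_flat), c(B, T_, m)))
}

## ---- dense + softmax + cross entropy ----

bdense_fwd <- function(H, params) {
  logits <- H %*% t(params$W) + matrix(params$b, nrow(H), length(params$b), byrow = TRUE)
  softmax_rows(logits)
}

# Combined softmax + cross-entropy backward: d logits = (P - onehot) / B.
bdense_bwd <- function(P, y, H, params) {
  B <- nrow(P)
  dlogit <- P
  dlogit[cbind(seq_len(B), y + 1L)] <- dlogit[cbind(seq_len(B), y + 1L)] - 1
  dlogit <- dlogit / B
  list(grads = list(W = crossprod(dlogit, H), b = colSums(dlogit)),
       dH = dlogit %*% params$W)
}

## ---- dropout ----

bdropout_fwd <- function(H, rate) {
  if (rate <= 0) return(list(out = H, mask = NULL))
  mask <- matrix(stats::runif(length(H)) >= rate, nrow(H), ncol(H)) / (1 - rate)
  list(out = H * mask, mask = mask)
}

bdropout_bwd <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}
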