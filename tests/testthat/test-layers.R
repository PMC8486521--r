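test_that("activation functions match their closed forms", {
  expect_equal(apply_activation("sigmoid", 0), 0.5)
  expect_equal(apply_activation("relu", c(-2.5, 3)), c(0, 3))
  expect_equal(apply_activation("softplus", 0), log(2))
  expect_equal(apply_activation("hard_sigmoid", c(-10, 0, 0.5, 10)),
               c(0, 0.5, 0.6, 1))
  expect_error(apply_activation("swish", 1), class = "medtext_usage_error")
  # sigma' = sigma (1 - sigma)
  z <- seq(-3, 3, by = 0.5)
  s <- apply_activation("sigmoid", z)
  num <- (apply_activation("sigmoid", z + 1e-6) -
            apply_activation("sigmoid", z - 1e-6)) / 2e-6
  expect_equal(num, s * (1 - s), tolerance = 1e-6)
})

test_that("text convolution matches hand sums and the nested-loop oracle", {
  bank <- conv_bank(2, 1, 1, activation = "linear", init = "zero")
  bank$filters[["2"]]$W <- matrix(c(1, 1), 1, 2)
  X <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(as.vector(conv1d_text(X, bank)[["2"]]), c(3, 5))

  zero_bank <- conv_bank(c(2, 3), 4, 3, activation = "relu", init = "zero")
  maps <- conv1d_text(matrix(0, 6, 3), zero_bank)
  expect_true(all(unlist(maps) == 0))

  withr::with_seed(10, {
    for (rep in 1:20) {
      n <- sample(5:8, 1); d <- sample(2:4, 1)
      bank <- conv_bank(c(2, 3), sample(2:4, 1), d,
                        activation = sample(c("relu", "linear", "tanh"), 1),
                        seed = rep)
      X <- rand_mat(n, d)
      got <- conv1d_text(X, bank)
      want <- oracle_conv1d(X, bank)
      expect_lt(max(abs(unlist(got) - unlist(want))), 1e-6)
    }
  })
  expect_error(conv1d_text(matrix(0, 2, 3), conv_bank(3, 2, 3)),
               class = "medtext_validation_error")
})

test_that("pooling reduces feature maps per filter", {
  m <- matrix(c(1, 4, 3), 3, 1)
  expect_equal(pool_time(m, "max"), 4)
  expect_equal(pool_time(m, "avg"), 8 / 3)
  cm <- matrix(2.5, 4, 2)
  expect_equal(pool_time(cm, "max"), c(2.5, 2.5))
  expect_equal(pool_time(cm, "avg"), c(2.5, 2.5))
  expect_error(pool_time(matrix(0, 0, 2), "max"), class = "medtext_validation_error")
})

test_that("lstm_step reproduces closed forms and the scalar oracle", {
  p0 <- lstm_params(2, 3, init = "zero")
  st <- lstm_step(c(0.5, -1), lstm_state(numeric(3)), p0)
  expect_equal(st$h, rep(0, 3))
  expect_equal(st$c, rep(0, 3))
  st1 <- lstm_step(c(0.5, -1), lstm_state(numeric(3), rep(1, 3)), p0)
  expect_equal(st1$c, rep(0.5, 3))
  expect_equal(st1$h, rep(0.5 * tanh(0.5), 3), tolerance = 1e-12)

  withr::with_seed(21, {
    for (rep in 1:20) {
      d <- sample(1:4, 1); H <- sample(1:4, 1)
      p <- lstm_params(d, H, seed = rep)
      x <- rnorm(d); h <- rnorm(H); cc <- rnorm(H)
      got <- lstm_step(x, lstm_state(h, cc), p)
      want <- oracle_lstm_step(x, h, cc, p)
      expect_lt(max(abs(got$h - want$h), abs(got$c - want$c)), 1e-6)
    }
  })
  expect_error(lstm_step(c(1, 2, 3), lstm_state(numeric(3)), p0),
               class = "medtext_validation_error")
})

test_that("lstm_sequence equals the explicit iteration of lstm_step", {
  p <- lstm_params(3, 2, seed = 5)
  X <- rand_mat(1, 3)
  single <- lstm_step(X[1, ], lstm_state(numeric(2)), p)
  seq1 <- lstm_sequence(X, p)
  expect_equal(seq1$outputs[1, ], single$h)

  withr::with_seed(31, {
    for (rep in 1:20) {
      T_ <- sample(2:6, 1); d <- sample(1:4, 1); H <- sample(1:4, 1)
      p <- lstm_params(d, H, seed = 100 + rep)
      X <- rand_mat(T_, d)
      got <- lstm_sequence(X, p)
      st <- lstm_state(numeric(H))
      for (t in seq_len(T_)) {
        o <- oracle_lstm_step(X[t, ], st$h, st$c, p)
        st <- lstm_state(o$h, o$c)
        expect_lt(max(abs(got$outputs[t, ] - o$h)), 1e-6)
      }
    }
  })
  zero <- lstm_sequence(rand_mat(4, 2), lstm_params(2, 3, init = "zero"))
  expect_true(all(zero$outputs == 0))
})

test_that("gru_step reproduces closed forms and the scalar oracle", {
  p0 <- gru_params(2, 3, init = "zero")
  expect_equal(gru_step(c(1, -1), rep(1, 3), p0), rep(0.5, 3))
  expect_equal(gru_step(c(1, -1), rep(0, 3), p0), rep(0, 3))
  withr::with_seed(41, {
    for (rep in 1:20) {
      d <- sample(1:4, 1); H <- sample(1:4, 1)
      p <- gru_params(d, H, seed = 200 + rep)
      x <- rnorm(d); h <- rnorm(H)
      expect_lt(max(abs(gru_step(x, h, p) - oracle_gru_step(x, h, p))), 1e-6)
    }
  })
})

test_that("bigru_sequence equals two independent directional runs", {
  p <- bigru_params(2, 3, seed = 7)
  X1 <- rand_mat(1, 2)
  out1 <- bigru_sequence(X1, p)
  expect_equal(out1[1, 1:3], gru_step(X1[1, ], numeric(3), p$forward))
  expect_equal(out1[1, 4:6], gru_step(X1[1, ], numeric(3), p$backward))

  # palindromic input with shared directional parameters: reversed symmetry
  ps <- p; ps$backward <- ps$forward
  Xp <- rbind(c(1, 2), c(3, 4), c(1, 2))
  outp <- bigru_sequence(Xp, ps)
  expect_equal(outp[, 1:3], outp[nrow(Xp):1, 4:6], tolerance = 1e-12)

  withr::with_seed(51, {
    for (rep in 1:20) {
      T_ <- sample(2:6, 1); d <- sample(1:3, 1); H <- sample(1:3, 1)
      p <- bigru_params(d, H, seed = 300 + rep)
      X <- rand_mat(T_, d)
      got <- bigru_sequence(X, p)
      # two-pass oracle: run each direction as a plain unidirectional GRU
      hf <- numeric(H); fw <- matrix(0, T_, H)
      for (t in seq_len(T_)) { hf <- oracle_gru_step(X[t, ], hf, p$forward); fw[t, ] <- hf }
      hb <- numeric(H); bw <- matrix(0, T_, H)
      for (t in rev(seq_len(T_))) { hb <- oracle_gru_step(X[t, ], hb, p$backward); bw[t, ] <- hb }
      expect_lt(max(abs(got - cbind(fw, bw))), 1e-6)
    }
  })
})

test_that("hybrid attention matches the direct formula evaluation", {
  p <- hybrid_attention_params(4, 3, seed = 2)
  H1 <- rand_mat(1, 4)
  out1 <- hybrid_attention(H1, p)
  expect_equal(unname(as.vector(out1)), as.vector(H1[1, ]))
  expect_equal(attr(out1, "weights"), 1)

  Hsame <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4)
  outs <- hybrid_attention(Hsame, p)
  expect_equal(attr(outs, "weights"), rep(0.2, 5))
  expect_equal(unname(as.vector(outs)), c(1, 2, 3, 4))

  withr::with_seed(61, {
    for (rep in 1:20) {
      T_ <- sample(2:8, 1); m <- sample(2:6, 1)
      p <- hybrid_attention_params(m, sample(2:5, 1), seed = 400 + rep)
      H <- rand_mat(T_, m)
      expect_lt(max(abs(as.vector(hybrid_attention(H, p)) -
                          oracle_hybrid_attention(H, p))), 1e-6)
    }
  })
})

test_that("scaled dot-product attention matches the nested-loop oracle", {
  V1 <- rand_mat(1, 3)
  expect_equal(unname(scaled_dot_attention(rand_mat(1, 3), rand_mat(1, 3), V1)[1, ]),
               V1[1, ])
  # identical keys: uniform weights, every output row the column mean of V
  K <- matrix(rep(c(1, 2), each = 4), 4, 2)
  Q <- rand_mat(4, 2); V <- rand_mat(4, 2)
  out <- scaled_dot_attention(Q, K, V)
  for (i in 1:4) expect_equal(out[i, ], colMeans(V), tolerance = 1e-12)

  withr::with_seed(71, {
    for (rep in 1:20) {
      n <- sample(2:6, 1); d <- sample(1:5, 1)
      Q <- rand_mat(n, d); K <- rand_mat(n, d); V <- rand_mat(n, d)
      expect_lt(max(abs(scaled_dot_attention(Q, K, V) - oracle_scaled_dot(Q, K, V))), 1e-6)
    }
  })
})

test_that("multihead attention reduces to scaled-dot and matches the per-head oracle", {
  d <- 4
  pid <- multihead_params(1, d, init = "identity")
  Q <- rand_mat(5, d); K <- rand_mat(5, d); V <- rand_mat(5, d)
  expect_equal(multihead_attention(Q, K, V, pid),
               scaled_dot_attention(Q, K, V), ignore_attr = TRUE)

  p2 <- multihead_params(2, 4, seed = 3)
  for (i in 1:2) p2$heads[[i]]$W_v <- matrix(0, 2, 4)
  expect_true(all(multihead_attention(Q, K, V, p2) == 0))

  withr::with_seed(81, {
    for (rep in 1:20) {
      nh <- sample(c(1, 2), 1); dm <- nh * sample(1:3, 1); n <- sample(2:6, 1)
      p <- multihead_params(nh, dm, seed = 500 + rep)
      Q <- rand_mat(n, dm); K <- rand_mat(n, dm); V <- rand_mat(n, dm)
      expect_lt(max(abs(multihead_attention(Q, K, V, p) -
                          oracle_multihead(Q, K, V, p))), 1e-6)
    }
  })
  expect_error(multihead_params(3, 4), class = "medtext_validation_error")
})

test_that("dense softmax produces valid probabilities with known values", {
  p0 <- dense_params(4, 3, init = "zero")
  expect_equal(dense_softmax(rnorm(4), p0), rep(1 / 3, 3))
  p <- dense_params(1, 2, init = "zero")
  p$W <- matrix(c(0, log(3)), 2, 1)
  expect_equal(dense_softmax(1, p), c(0.25, 0.75))
  withr::with_seed(91, {
    for (rep in 1:10) {
      pp <- dense_params(5, 4, seed = rep)
      out <- dense_softmax(rnorm(5), pp)
      expect_true(all(out > 0))
      expect_lt(abs(sum(out) - 1), 1e-9)
    }
  })
})

test_that("cross-entropy loss matches its closed forms", {
  expect_lt(cross_entropy_loss(matrix(c(0, 1), 1, 2), 1L), 1e-6)
  expect_equal(cross_entropy_loss(0.5, 1L), log(2), tolerance = 1e-7)
  withr::with_seed(101, {
    P <- softmax_rows_ref(rand_mat(6, 3))
    y <- sample(0:2, 6, replace = TRUE)
    per <- vapply(1:6, function(i) cross_entropy_loss(P[i, , drop = FALSE], y[i]), 0)
    expect_equal(cross_entropy_loss(P, y), mean(per), tolerance = 1e-12)
  })
  expect_error(cross_entropy_loss(matrix(0.5, 1, 2), 2L), class = "medtext_validation_error")
})

test_that("attention weights are simplex vectors; recurrences stay bounded", {
  withr::with_seed(111, {
    for (rep in 1:100) {
      T_ <- sample(1:8, 1); m <- sample(2:5, 1)
      H <- rand_mat(T_, m) * 3
      w <- attr(hybrid_attention(H, hybrid_attention_params(m, 3, seed = rep)), "weights")
      expect_true(all(w >= 0))
      expect_lt(abs(sum(w) - 1), 1e-9)
      n <- sample(2:6, 1); d <- sample(1:4, 1)
      A <- attr(scaled_dot_attention(rand_mat(n, d), rand_mat(n, d), rand_mat(n, d)),
                "weights")
      expect_true(all(A >= 0))
      expect_lt(max(abs(rowSums(A) - 1)), 1e-9)
    }
    # |h| <= 1 componentwise for arbitrary finite inputs
    for (rep in 1:25) {
      d <- sample(1:4, 1); H <- sample(1:4, 1)
      p <- lstm_params(d, H, seed = rep)
      st <- lstm_step(rnorm(d, sd = 50), lstm_state(rnorm(H), rnorm(H, sd = 10)), p)
      expect_true(all(abs(st$h) <= 1))
      # GRU output is a convex combination of h_prev and the candidate
      pg <- gru_params(d, H, seed = rep)
      x <- rnorm(d); h0 <- rnorm(H)
      A <- c(h0, x)
      z <- 1 / (1 + exp(-drop(pg$W_z %*% A)))
      r <- 1 / (1 + exp(-drop(pg$W_r %*% A)))
      htil <- tanh(drop(pg$W %*% c(r * h0, x)))
      h1 <- gru_step(x, h0, pg)
      expect_true(all(h1 >= pmin(h0, htil) - 1e-12 & h1 <= pmax(h0, htil) + 1e-12))
    }
  })
})

test_that("the dense-softmax cross-entropy gradient passes a finite-difference check", {
  withr::with_seed(121, {
    D <- 5; C <- 3; N <- 4
    p <- dense_params(D, C, seed = 9)
    H <- rand_mat(N, D)
    y <- sample(0:(C - 1), N, replace = TRUE)
    fwd <- function(W, b) {
      logits <- H %*% t(W) + matrix(b, N, C, byrow = TRUE)
      e <- exp(logits - apply(logits, 1, max))
      P <- e / rowSums(e)
      cross_entropy_loss(P, y)
    }
    # analytic gradient via the combined softmax + cross-entropy backward
    logits <- H %*% t(p$W) + matrix(p$b, N, C, byrow = TRUE)
    e <- exp(logits - apply(logits, 1, max)); P <- e / rowSums(e)
    dlog <- P; dlog[cbind(1:N, y + 1)] <- dlog[cbind(1:N, y + 1)] - 1
    dlog <- dlog / N
    gW <- t(dlog) %*% H; gb <- colSums(dlog)
    eps <- 1e-6
    for (k in 1:12) {
      i <- sample(length(p$W), 1)
      Wp <- p$W; Wp[i] <- Wp[i] + eps
      Wm <- p$W; Wm[i] <- Wm[i] - eps
      num <- (fwd(Wp, p$b) - fwd(Wm, p$b)) / (2 * eps)
      expect_equal(num, gW[i], tolerance = 1e-4)
    }
    for (i in seq_len(C)) {
      bp <- p$b; bp[i] <- bp[i] + eps
      bm <- p$b; bm[i] <- bm[i] - eps
      expect_equal((fwd(p$W, bp) - fwd(p$W, bm)) / (2 * eps), gb[i], tolerance = 1e-4)
    }
  })
})
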