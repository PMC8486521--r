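#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length; neither may be all zero.
#' @return `u . v / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop_validation("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_validation("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Seeded random embedding matrix
#'
#' Uniform initialization in `[-0.5/d, 0.5/d]`, the customary word2vec input
#' layer initialization. Useful as a from-scratch starting point when
#' skip-gram pretraining is not wanted.
#'
#' @param vocab A `vocabulary`.
#' @param d Embedding dimension (>= 2).
#' @param seed Integer seed.
#' @return An `embedding_matrix`.
#' @export
random_embedding <- function(vocab, d, seed = 1L) {
  check_scalar_number(d, "d", lower = 2)
  mat <- withr::with_seed(as.integer(seed), {
    matrix(stats::runif(vocab$size * d, -0.5, 0.5) / d, vocab$size, d)
  })
  rownames(mat) <- vocab$tokens
  new_embedding(vocab$level, mat, vocab)
}

new_embedding <- function(level, mat, vocab, loss = numeric(0)) {
  structure(list(level = level, matrix = mat, d = ncol(mat),
                 vocab = vocab, loss = loss),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> level=%s vocab=%d d=%d\n",
              x$level, nrow(x$matrix), x$d))
  invisible(x)
}

sigmoid_scalar <- function(z) 1 / (1 + exp(-z))

#' Train skip-gram (word2vec) embeddings with negative sampling
#'
#' The center token predicts each context token within `window` positions;
#' every positive pair is contrasted against `negatives` tokens drawn from
#' the unigram distribution raised to the 3/4 power. Optimized by SGD on the
#' negative-sampling logistic loss. All randomness (initialization, pair
#' shuffling, negative draws) derives from `seed`.
#'
#' @param corpus A `labeled_corpus`.
#' @param level `"word"` or `"char"`.
#' @param vocab Optional prebuilt `vocabulary` (built from `corpus` if NULL).
#' @param d Embedding dimension (default 100 for words, 50 for characters).
#' @param window Context radius in tokens (default 5).
#' @param negatives Negative samples per positive pair (default 5).
#' @param epochs Training epochs (default 5; 0 returns the seeded random
#'   initialization unchanged).
#' @param lr SGD learning rate (default 0.025).
#' @param min_count Vocabulary threshold when `vocab` is NULL.
#' @param seed Integer seed.
#' @return An `embedding_matrix` whose `loss` element holds the mean
#'   per-pair loss of each epoch.
#' @export
train_skipgram <- function(corpus, level = c("word", "char"), vocab = NULL,
                           d = NULL, window = 5L, negatives = 5L,
                           epochs = 5L, lr = 0.025, min_count = 1L, seed = 1L) {
  level <- match.arg(level)
  corpus <- as_labeled_corpus(corpus, normalize = FALSE)
  if (is.null(vocab)) vocab <- build_vocab(corpus, level, min_count)
  if (is.null(d)) d <- if (level == "word") 100L else 50L
  check_scalar_number(d, "d", lower = 2)
  check_scalar_number(window, "window", lower = 1)
  check_scalar_number(negatives, "negatives", lower = 1)
  check_scalar_number(epochs, "epochs", lower = 0)
  check_scalar_number(lr, "lr")
  if (lr <= 0) stop_validation("`lr` must be positive")

  seqs <- lapply(tokenize_corpus(corpus, level), function(tk) {
    idx <- tokens_to_indices(tk, vocab)
    idx[idx >= 2L]  # reserved pad/unk rows are not trained
  })
  seqs <- seqs[lengths(seqs) >= 2L]
  if (!length(seqs)) {
    stop_validation("no context pairs: every document has fewer than 2 in-vocabulary tokens")
  }

  V <- vocab$size
  withr::with_seed(as.integer(seed), {
    W_in <- matrix(stats::runif(V * d, -0.5, 0.5) / d, V, d)
    W_out <- matrix(0, V, d)

    # all (center, context) pairs up front; 1-based row indices
    pairs <- do.call(rbind, lapply(seqs, function(s) {
      n <- length(s)
      ij <- do.call(rbind, lapply(seq_len(n), function(i) {
        lo <- max(1L, i - window); hi <- min(n, i + window)
        ctx <- setdiff(lo:hi, i)
        if (length(ctx)) cbind(s[i] + 1L, s[ctx] + 1L) else NULL
      }))
      ij
    }))

    # negative-sampling table: unigram^0.75 over trainable tokens
    trainable <- 3:V
    uf <- as.numeric(vocab$freq)^0.75
    neg_prob <- uf / sum(uf)

    k <- as.integer(negatives)
    history <- numeric(0)
    chunk <- 4096L
    for (ep in seq_len(as.integer(epochs))) {
      ord <- sample.int(nrow(pairs))
      total_loss <- 0
      starts <- seq(1L, nrow(pairs), by = chunk)
      for (st in starts) {
        rows <- ord[st:min(st + chunk - 1L, nrow(pairs))]
        m <- length(rows)
        ci <- pairs[rows, 1L]; oi <- pairs[rows, 2L]
        negs <- matrix(sample(trainable, m * k, replace = TRUE, prob = neg_prob), m, k)
        tgt <- cbind(oi, negs)                       # [m x (k+1)]
        lab <- c(1, rep(0, k))
        v <- W_in[ci, , drop = FALSE]
        dv <- matrix(0, m, d)
        tgt_flat <- as.vector(tgt)
        du_flat <- matrix(0, m * (k + 1L), d)
        for (j in seq_len(k + 1L)) {
          u <- W_out[tgt[, j], , drop = FALSE]
          s <- sigmoid_scalar(rowSums(v * u))
          g <- s - lab[j]
          dv <- dv + g * u
          du_flat[(j - 1L) * m + seq_len(m), ] <- g * v
          p <- if (lab[j] == 1) s else 1 - s
          total_loss <- total_loss - sum(log(pmax(p, 1e-10)))
        }
        gin <- rowsum(dv, group = ci)
        ri <- as.integer(rownames(gin))
        W_in[ri, ] <- W_in[ri, ] - lr * gin
        gout <- rowsum(du_flat, group = tgt_flat)
        ro <- as.integer(rownames(gout))
        W_out[ro, ] <- W_out[ro, ] - lr * gout
      }
      history <- c(history, total_loss / nrow(pairs))
    }
  })
  rownames(W_in) <- vocab$tokens
  new_embedding(level, W_in, vocab, loss = history)
}

#' Write an embedding matrix in the word2vec text format
#'
#' First line `"<vocab_size> <d>"`, then one `token v1 ... vd` line per row.
#'
#' @param emb An `embedding_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  mat <- emb$matrix
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(rownames(mat)[i], paste(formatC(mat[i, ], format = "g", digits = 8),
                                  collapse = " "))
  }, "")
  writeLines(c(paste(nrow(mat), ncol(mat)), body), path, useBytes = TRUE)
  invisible(path)
}

#' Read an embedding matrix from the word2vec text format
#'
#' @param path Input file.
#' @param level `"word"` or `"char"` (recorded on the result).
#' @return An `embedding_matrix` (with a minimal vocabulary rebuilt from the
#'   token column).
#' @export
read_embedding <- function(path, level = c("word", "char")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  v <- hdr[1]; d <- hdr[2]
  parts <- strsplit(lines[1 + seq_len(v)], " ", fixed = TRUE)
  tokens <- vapply(parts, `[[`, "", 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(mat) <- tokens
  vocab <- structure(
    list(level = level, tokens = tokens,
         index = stats::setNames(seq_along(tokens) - 1L, tokens),
         freq = NULL, size = length(tokens)),
    class = "vocabulary"
  )
  new_embedding(level, mat, vocab)
}
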