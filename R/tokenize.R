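#' Tokenize text at word or character level
#'
#' Word level splits normalized text on spaces; character level yields every
#' character, with the space rendered as the sentinel token `"_"` so that
#' token boundaries remain visible to character models.
#'
#' @param text A single string (assumed normalized, see [normalize_text()]).
#' @param level `"word"` or `"char"`.
#' @return Character vector of tokens (empty for empty text).
#' @export
#' @examples
#' tokenize("tumor growth", "word")
#' tokenize("ab c", "char")
tokenize <- function(text, level = c("word", "char")) {
  level <- match.arg(level)
  if (length(text) != 1L) stop_validation("`text` must be a single string")
  if (is.na(text) || text == "") return(character(0))
  if (level == "word") {
    strsplit(text, " ", fixed = TRUE)[[1]]
  } else {
    ch <- strsplit(text, "", fixed = TRUE)[[1]]
    ch[ch == " "] <- "_"
    ch
  }
}

tokenize_corpus <- function(corpus, level) {
  lapply(corpus$text, tokenize, level = level)
}

PAD_INDEX <- 0L
UNK_INDEX <- 1L

#' Build a vocabulary from a corpus
#'
#' Indices 0 and 1 are reserved for the padding and unknown tokens. The
#' remaining entries are ordered by descending corpus frequency with ties
#' broken lexicographically; tokens rarer than `min_count` are dropped (they
#' encode to the unknown index).
#'
#' @param corpus A `labeled_corpus`.
#' @param level `"word"` or `"char"`.
#' @param min_count Minimum corpus frequency to keep a token (default 1).
#' @return A `vocabulary` object.
#' @export
build_vocab <- function(corpus, level = c("word", "char"), min_count = 1L) {
  level <- match.arg(level)
  corpus <- as_labeled_corpus(corpus, normalize = FALSE)
  check_scalar_number(min_count, "min_count", lower = 1)
  toks <- unlist(tokenize_corpus(corpus, level), use.names = FALSE)
  freq <- table(toks)
  freq <- freq[freq >= min_count]
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  kept <- names(freq)[ord]
  tokens <- c("<pad>", "<unk>", kept)
  index <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(
    list(level = level, tokens = tokens, index = index,
         freq = stats::setNames(as.integer(freq)[ord], kept),
         size = length(tokens)),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> level=%s size=%d (incl. <pad>, <unk>)\n", x$level, x$size))
  invisible(x)
}

#' Map tokens to indices
#'
#' @param tokens Character vector of tokens.
#' @param vocab A `vocabulary`.
#' @return Integer indices (0-based; unknown tokens map to 1).
#' @export
tokens_to_indices <- function(tokens, vocab) {
  idx <- vocab$index[tokens]
  idx[is.na(idx)] <- UNK_INDEX
  unname(idx)
}

#' Map indices back to tokens
#'
#' @param indices Integer vector of 0-based indices.
#' @param vocab A `vocabulary`.
#' @return Character vector of tokens.
#' @export
indices_to_tokens <- function(indices, vocab) {
  if (any(indices < 0L | indices >= vocab$size)) {
    stop_validation("index out of vocabulary range")
  }
  vocab$tokens[indices + 1L]
}

#' Encode a token sequence to a fixed-length index vector
#'
#' Sequences longer than `max_len` are truncated at the tail (leading tokens
#' kept); shorter sequences are padded at the tail with the padding index 0.
#'
#' @param tokens Character vector of tokens.
#' @param vocab A `vocabulary`.
#' @param max_len Target length (>= 1).
#' @return Integer vector of length `max_len` (0-based indices).
#' @export
#' @examples
#' v <- build_vocab(as_labeled_corpus(data.frame(text = "a b c", label = "x")), "word")
#' encode_pad(c("a", "b"), v, 4)
encode_pad <- function(tokens, vocab, max_len) {
  check_scalar_number(max_len, "max_len", lower = 1)
  max_len <- as.integer(max_len)
  idx <- tokens_to_indices(tokens, vocab)
  if (length(idx) >= max_len) {
    idx[seq_len(max_len)]
  } else {
    c(idx, rep(PAD_INDEX, max_len - length(idx)))
  }
}

#' Encode a corpus into fixed-length index matrices
#'
#' Produces the padded word-level (and optionally character-level) index
#' matrices and the 0-based integer label vector that the model forward
#' passes consume.
#'
#' @param corpus A `labeled_corpus`.
#' @param word_vocab Word-level `vocabulary`.
#' @param n_w Word sequence length.
#' @param char_vocab Optional character-level `vocabulary`.
#' @param n_c Character sequence length (required with `char_vocab`).
#' @return An `encoded_batch`: list with `word` (integer matrix
#'   `[n_docs x n_w]`), `char` (matrix or NULL), `labels` (0-based integer
#'   vector), `classes`, `doc_ids`, `n_w`, `n_c`.
#' @export
encode_corpus <- function(corpus, word_vocab, n_w, char_vocab = NULL, n_c = NULL) {
  corpus <- as_labeled_corpus(corpus, normalize = FALSE)
  classes <- class_names(corpus)
  word <- t(vapply(corpus$text,
                   function(tx) encode_pad(tokenize(tx, "word"), word_vocab, n_w),
                   integer(n_w)))
  dimnames(word) <- NULL
  chr <- NULL
  if (!is.null(char_vocab)) {
    if (is.null(n_c)) stop_validation("`n_c` is required when `char_vocab` is given")
    chr <- t(vapply(corpus$text,
                    function(tx) encode_pad(tokenize(tx, "char"), char_vocab, n_c),
                    integer(n_c)))
    dimnames(chr) <- NULL
  }
  structure(
    list(word = word, char = chr,
         labels = match(corpus$label, classes) - 1L,
         classes = classes, doc_ids = corpus$doc_id,
         n_w = as.integer(n_w), n_c = if (is.null(n_c)) NULL else as.integer(n_c)),
    class = "encoded_batch"
  )
}

#' @export
print.encoded_batch <- function(x, ...) {
  cat(sprintf("<encoded_batch> %d docs, n_w=%d%s, %d classes\n",
              nrow(x$word), x$n_w,
              if (!is.null(x$char)) sprintf(", n_c=%d", x$n_c) else "",
              length(x$classes)))
  invisible(x)
}

subset_batch <- function(batch, rows) {
  structure(
    list(word = batch$word[rows, , drop = FALSE],
         char = if (!is.null(batch$char)) batch$char[rows, , drop = FALSE] else NULL,
         labels = batch$labels[rows],
         classes = batch$classes, doc_ids = batch$doc_ids[rows],
         n_w = batch$n_w, n_c = batch$n_c),
    class = "encoded_batch"
  )
}
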