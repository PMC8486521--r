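#' Specification for a synthetic labeled corpus
#'
#' The generator produces class-balanced corpora whose class signal is
#' controllable at two granularities: word-level keywords (disjoint sets of
#' class-specific tokens injected at a per-token rate) and character-level
#' motifs (a short class-specific character string embedded inside otherwise
#' random tokens, which are therefore near-unique at the word level). Labels
#' can be corrupted at a given noise rate. Defaults describe the corpus used
#' throughout the package's reduced-size experiments.
#'
#' @param n_docs Number of documents (default 2000).
#' @param n_classes Number of classes (default 2).
#' @param doc_len Length range in word tokens, `c(min, max)`
#'   (default `c(20, 40)`).
#' @param bg_vocab Background vocabulary size (default 500).
#' @param keywords_per_class Keywords per class (default 8).
#' @param keyword_rate Per-token probability of emitting a class keyword
#'   (default 0.15).
#' @param char_rate Per-token probability of emitting a random token with
#'   the class motif embedded (default 0.5).
#' @param motif_len Motif length in characters, 3-6 (default 4).
#' @param label_noise Probability that a document's label is replaced by a
#'   uniform draw over all classes (default 0).
#' @param keywords Optional explicit per-class keyword list (pairwise
#'   disjoint character vectors).
#' @param seed Integer seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_docs = 2000L, n_classes = 2L, doc_len = c(20L, 40L),
                       bg_vocab = 500L, keywords_per_class = 8L,
                       keyword_rate = 0.15, char_rate = 0.5, motif_len = 4L,
                       label_noise = 0, keywords = NULL, seed = 1L) {
  check_scalar_number(n_docs, "n_docs", lower = 2)
  check_scalar_number(n_classes, "n_classes", lower = 2)
  check_scalar_number(keyword_rate, "keyword_rate", lower = 0, upper = 1)
  check_scalar_number(char_rate, "char_rate", lower = 0, upper = 1)
  check_scalar_number(label_noise, "label_noise", lower = 0, upper = 0.999)
  check_scalar_number(motif_len, "motif_len", lower = 3, upper = 6)
  if (length(doc_len) != 2L || doc_len[1] > doc_len[2] || doc_len[1] < 1) {
    stop_validation("`doc_len` must be c(min, max) with 1 <= min <= max")
  }
  if (!is.null(keywords)) {
    if (length(keywords) != n_classes) {
      stop_validation("`keywords` must have one element per class")
    }
    all_kw <- unlist(keywords)
    if (anyDuplicated(all_kw)) stop_validation("keyword sets must be pairwise disjoint")
  }
  structure(list(n_docs = as.integer(n_docs), n_classes = as.integer(n_classes),
                 doc_len = as.integer(doc_len), bg_vocab = as.integer(bg_vocab),
                 keywords_per_class = as.integer(keywords_per_class),
                 keyword_rate = keyword_rate, char_rate = char_rate,
                 motif_len = as.integer(motif_len), label_noise = label_noise,
                 keywords = keywords, seed = as.integer(seed)),
            class = "synth_spec")
}

random_tokens <- function(n, len_range = c(3L, 8L)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  vapply(lens, function(l) paste(sample(letters, l, replace = TRUE), collapse = ""), "")
}

unique_random_tokens <- function(n, len_range = c(3L, 8L), taken = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    cand <- setdiff(unique(random_tokens(n, len_range)), c(taken, out))
    out <- c(out, cand)[seq_len(min(n, length(out) + length(cand)))]
  }
  out
}

#' Generate a synthetic labeled corpus
#'
#' Documents are sequences of background tokens (uniform over a fixed
#' background vocabulary of random lowercase strings); each token position
#' independently becomes a class keyword with probability `keyword_rate`,
#' or otherwise a freshly random token with the class's character motif
#' embedded with probability `char_rate`. Class counts are exactly balanced
#' (within 1) and labels are then corrupted at the `label_noise` rate. The
#' whole construction is a deterministic function of `spec$seed`. The true
#' keyword sets and motifs are attached as attributes (`"keywords"`,
#' `"char_motifs"`) for use by [separability_check()].
#'
#' @param spec A [synth_spec()].
#' @return A `labeled_corpus`.
#' @export
generate_corpus <- function(spec = synth_spec()) {
  if (!inherits(spec, "synth_spec")) stop_validation("`spec` must be a synth_spec")
  C <- spec$n_classes
  classes <- sprintf("c%02d", seq_len(C))
  withr::with_seed(spec$seed, {
    bg <- unique_random_tokens(spec$bg_vocab)
    if (is.null(spec$keywords)) {
      kw_flat <- unique_random_tokens(C * spec$keywords_per_class, taken = bg)
      keywords <- split(kw_flat, rep(classes, each = spec$keywords_per_class))
    } else {
      keywords <- stats::setNames(spec$keywords, classes)
    }
    motifs <- stats::setNames(unique_random_tokens(C, c(spec$motif_len, spec$motif_len)),
                              classes)
    # exact balance (+-1), then shuffled
    true_lab <- sample(rep_len(classes, spec$n_docs))
    texts <- vapply(seq_len(spec$n_docs), function(i) {
      len <- sample(spec$doc_len[1]:spec$doc_len[2], 1L)
      cls <- true_lab[i]
      u <- stats::runif(len)
      toks <- character(len)
      is_kw <- u < spec$keyword_rate
      is_motif <- !is_kw & (u < spec$keyword_rate + (1 - spec$keyword_rate) * spec$char_rate)
      n_kw <- sum(is_kw)
      if (n_kw) toks[is_kw] <- sample(keywords[[cls]], n_kw, replace = TRUE)
      n_m <- sum(is_motif)
      if (n_m) {
        # carriers long enough that motif-bearing tokens are effectively
        # unique strings: the class signal stays invisible at word level
        carriers <- random_tokens(n_m, c(6L, 9L))
        toks[is_motif] <- vapply(carriers, function(tk) {
          pos <- sample.int(nchar(tk) + 1L, 1L) - 1L
          paste0(substr(tk, 1, pos), motifs[[cls]],
                 substr(tk, pos + 1L, nchar(tk)))
        }, "", USE.NAMES = FALSE)
      }
      n_bg <- sum(!is_kw & !is_motif)
      if (n_bg) toks[!is_kw & !is_motif] <- sample(bg, n_bg, replace = TRUE)
      paste(toks, collapse = " ")
    }, "")
    obs_lab <- true_lab
    if (spec$label_noise > 0) {
      flip <- stats::runif(spec$n_docs) < spec$label_noise
      obs_lab[flip] <- sample(classes, sum(flip), replace = TRUE)
    }
    corp <- as_labeled_corpus(tibble::tibble(text = texts, label = obs_lab),
                              normalize = FALSE)
    attr(corp, "class_names") <- classes
    attr(corp, "keywords") <- keywords
    attr(corp, "char_motifs") <- motifs
    corp
  })
}

#' Accuracy of a keyword-presence decision rule
#'
#' Classifies each document by the class whose keyword set has most distinct
#' members among the document's word tokens (ties broken uniformly at
#' random, seeded), and reports the resulting accuracy against the corpus
#' labels. A purely word-level baseline: corpora whose signal lives only in
#' character motifs score at chance.
#'
#' @param corpus A `labeled_corpus` carrying a `"keywords"` attribute (as
#'   produced by [generate_corpus()]), or supply `keywords` explicitly.
#' @param keywords Optional named list of per-class keyword vectors.
#' @param seed Seed for tie breaking.
#' @return Accuracy in `[0, 1]`.
#' @export
separability_check <- function(corpus, keywords = NULL, seed = 1L) {
  keywords <- keywords %||% attr(corpus, "keywords")
  if (is.null(keywords)) stop_validation("no keyword sets available")
  classes <- names(keywords)
  withr::with_seed(as.integer(seed), {
    preds <- vapply(corpus$text, function(tx) {
      toks <- unique(tokenize(tx, "word"))
      hits <- vapply(keywords, function(kw) length(intersect(toks, kw)), 0L)
      top <- which(hits == max(hits))
      classes[if (length(top) == 1L) top else sample(top, 1L)]
    }, "", USE.NAMES = FALSE)
  })
  mean(preds == corpus$label)
}
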