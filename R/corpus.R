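#' Normalize document text
#'
#' Lowercases and collapses all runs of whitespace to single spaces. This is
#' the only text normalization applied anywhere in the package: no stemming,
#' no stop-word removal, so tokenization stays invertible.
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_text("  Tumor   GROWTH\n factor ")
normalize_text <- function(text) {
  tolower(trimws(gsub("\\s+", " ", text)))
}

#' Construct a labeled corpus
#'
#' A labeled corpus is a tibble with columns `doc_id`, `text` and `label`,
#' carrying the sorted class names in the `class_names` attribute. It is the
#' universal input to every downstream stage (tokenization, embedding
#' training, model fitting).
#'
#' @param df Data frame with columns `text` and `label` (and optionally
#'   `doc_id`; ids are generated when absent).
#' @param normalize Apply [normalize_text()] to the text column (default TRUE).
#' @return A `labeled_corpus` tibble.
#' @export
as_labeled_corpus <- function(df, normalize = TRUE) {
  if (!is.data.frame(df)) stop_validation("`df` must be a data frame")
  if (!all(c("text", "label") %in% names(df))) {
    stop_validation("corpus needs `text` and `label` columns")
  }
  if (nrow(df) == 0L) stop_validation("corpus is empty")
  out <- tibble::as_tibble(df[, intersect(c("doc_id", "text", "label"), names(df))])
  if (!"doc_id" %in% names(out)) {
    out$doc_id <- sprintf("doc%05d", seq_len(nrow(out)))
  }
  out <- out[, c("doc_id", "text", "label")]
  out$doc_id <- as.character(out$doc_id)
  out$text <- if (normalize) normalize_text(as.character(out$text)) else as.character(out$text)
  out$label <- as.character(out$label)
  if (anyDuplicated(out$doc_id)) stop_validation("doc_ids must be unique")
  if (anyNA(out$label) || any(out$label == "")) stop_validation("labels must be non-missing")
  blank <- which(is.na(out$text) | out$text == "")
  if (length(blank)) {
    stop_validation(sprintf("blank text field at record %s", paste(blank, collapse = ", ")))
  }
  attr(out, "class_names") <- sort(unique(out$label))
  class(out) <- c("labeled_corpus", class(out))
  out
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat(sprintf("<labeled_corpus> %d documents, %d classes (%s)\n",
              nrow(x), length(class_names(x)),
              paste(class_names(x), collapse = ", ")))
  NextMethod()
}

#' Class names of a labeled corpus
#' @param corpus A `labeled_corpus`.
#' @return Character vector of sorted class names.
#' @export
class_names <- function(corpus) {
  attr(corpus, "class_names") %||% sort(unique(corpus$label))
}

detect_delim <- function(header_line) {
  if (grepl("\t", header_line)) "\t" else ","
}

#' Read a labeled corpus from disk
#'
#' Two plain-text layouts are supported:
#' \describe{
#'   \item{`delimited`}{UTF-8 file with a header row `text,label` (comma- or
#'     tab-separated, auto-detected from the header), one document per row.}
#'   \item{`per_class_files`}{One `<class>.txt` file per class, one document
#'     per line; labels are taken from the file stems. `path` may be a
#'     directory containing the files or a character vector of file paths.}
#' }
#' Text is normalized with [normalize_text()] and class names are sorted
#' lexicographically.
#'
#' @param path File, directory, or vector of per-class files.
#' @param format `"delimited"` or `"per_class_files"`.
#' @return A `labeled_corpus`.
#' @export
read_corpus <- function(path, format = c("delimited", "per_class_files")) {
  if (length(format) != 1L || !format %in% c("delimited", "per_class_files")) {
    format <- tryCatch(match.arg(format), error = function(e) {
      stop_usage(sprintf("unknown corpus format '%s'", paste(format, collapse = "/")))
    })
  }
  if (format == "delimited") {
    if (length(path) != 1L || !file.exists(path)) {
      stop_io(sprintf("file not found: %s", paste(path, collapse = ", ")))
    }
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (length(lines) < 2L) stop_validation("empty corpus (no data rows)")
    sep <- detect_delim(lines[1])
    header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
    if (!all(c("text", "label") %in% header)) {
      stop_validation("delimited corpus must have header columns `text` and `label`")
    }
    parts <- strsplit(lines[-1], sep, fixed = TRUE)
    ti <- match("text", header); li <- match("label", header)
    txt <- vapply(parts, function(p) if (length(p) >= ti) p[ti] else "", "")
    lab <- vapply(parts, function(p) if (length(p) >= li) p[li] else "", "")
    ntxt <- normalize_text(txt)
    blank <- which(ntxt == "" | is.na(ntxt))
    if (length(blank)) {
      stop_validation(sprintf("blank text field at line %s of %s",
                              paste(blank + 1L, collapse = ", "), path))
    }
    return(as_labeled_corpus(tibble::tibble(text = ntxt, label = lab)))
  }
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.txt$", full.names = TRUE)
  } else {
    path
  }
  missing <- files[!file.exists(files)]
  if (length(missing)) stop_io(sprintf("file not found: %s", paste(missing, collapse = ", ")))
  if (!length(files)) stop_validation("no per-class .txt files found")
  files <- files[order(basename(files))]
  docs <- purrr::map_dfr(files, function(f) {
    cls <- sub("\\.txt$", "", basename(f))
    lines <- readLines(f, encoding = "UTF-8", warn = FALSE)
    norm <- normalize_text(lines)
    blank <- which(norm == "")
    if (length(blank)) {
      stop_validation(sprintf("blank text field at line %s of %s",
                              paste(blank, collapse = ", "), f))
    }
    tibble::tibble(text = norm, label = cls)
  })
  if (nrow(docs) == 0L) stop_validation("empty corpus")
  as_labeled_corpus(docs)
}

#' Write a labeled corpus as a delimited file
#'
#' @param corpus A `labeled_corpus`.
#' @param path Output file.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, sep = "\t") {
  corpus <- as_labeled_corpus(corpus)
  lines <- c(paste("text", "label", sep = sep),
             paste(corpus$text, corpus$label, sep = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Deterministically split a corpus into train/validation/test sets
#'
#' Sizes follow the floor rule: `|val| = floor(val_frac * n)`,
#' `|test| = floor(test_frac * n)`, and the remainder goes to the training
#' set. With `stratified = TRUE` the same rule is applied within each class.
#' Shuffling is driven only by `seed`, so the same seed always yields the
#' same membership lists.
#'
#' @param corpus A `labeled_corpus`.
#' @param train_frac,val_frac,test_frac Proportions in (0,1) summing to 1.
#' @param seed Integer seed controlling the shuffle.
#' @param stratified Apply the floor rule per class (default FALSE).
#' @return Named list with elements `train`, `val`, `test`, each a
#'   `labeled_corpus`.
#' @export
#' @examples
#' corp <- as_labeled_corpus(data.frame(
#'   text = paste("doc", 1:10), label = rep(c("a", "b"), 5)))
#' vapply(split_corpus(corp, seed = 1), nrow, 0L)
split_corpus <- function(corpus, train_frac = 0.7, val_frac = 0.2,
                         test_frac = 0.1, seed = 1L, stratified = FALSE) {
  corpus <- as_labeled_corpus(corpus, normalize = FALSE)
  for (f in c(train_frac, val_frac, test_frac)) {
    check_scalar_number(f, "split fraction")
    if (f <= 0 || f >= 1) stop_validation("split fractions must lie in (0, 1)")
  }
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9) {
    stop_validation("split fractions must sum to 1")
  }
  take <- function(rows) {
    n <- length(rows)
    n_val <- floor(val_frac * n)
    n_test <- floor(test_frac * n)
    n_train <- n - n_val - n_test
    list(train = rows[seq_len(n_train)],
         val = rows[n_train + seq_len(n_val)],
         test = rows[n_train + n_val + seq_len(n_test)])
  }
  parts <- withr::with_seed(as.integer(seed), {
    if (stratified) {
      by_class <- split(seq_len(nrow(corpus)), corpus$label)
      pieces <- lapply(by_class, function(rows) take(sample(rows)))
      list(train = unlist(lapply(pieces, `[[`, "train"), use.names = FALSE),
           val = unlist(lapply(pieces, `[[`, "val"), use.names = FALSE),
           test = unlist(lapply(pieces, `[[`, "test"), use.names = FALSE))
    } else {
      take(sample.int(nrow(corpus)))
    }
  })
  if (any(vapply(parts, length, 0L) == 0L)) {
    stop_validation("corpus too small: a split would be empty")
  }
  out <- lapply(parts, function(rows) {
    sub <- corpus[rows, ]
    attr(sub, "class_names") <- class_names(corpus)
    attr(sub, "keywords") <- attr(corpus, "keywords")
    attr(sub, "char_motifs") <- attr(corpus, "char_motifs")
    class(sub) <- class(corpus)
    sub
  })
  structure(out, class = "corpus_split")
}

#' Write split membership manifests
#'
#' Writes `train.txt`, `val.txt` and `test.txt`, one doc_id per line, into
#' `dir`.
#'
#' @param split Result of [split_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_split_manifest <- function(split, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("train", "val", "test")) {
    writeLines(split[[nm]]$doc_id, file.path(dir, paste0(nm, ".txt")))
  }
  invisible(dir)
}

#' Summary statistics of a labeled corpus
#'
#' @param corpus A `labeled_corpus`.
#' @return One-row tibble with `n_docs`, `n_classes`, `max_length`,
#'   `mean_length` (word tokens), `vocab_size` (distinct word tokens) and a
#'   `class_counts` list column (named integer vector).
#' @export
corpus_stats <- function(corpus) {
  corpus <- as_labeled_corpus(corpus, normalize = FALSE)
  toks <- strsplit(corpus$text, " ", fixed = TRUE)
  lens <- lengths(toks)
  counts <- table(factor(corpus$label, levels = class_names(corpus)))
  tibble::tibble(
    n_docs = nrow(corpus),
    n_classes = length(class_names(corpus)),
    max_length = max(lens),
    mean_length = mean(lens),
    vocab_size = length(unique(unlist(toks))),
    class_counts = list(stats::setNames(as.integer(counts), names(counts)))
  )
}
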