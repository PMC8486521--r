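#' One-vs-rest confusion counts
#'
#' For each class, counts true/false positives and negatives treating that
#' class as positive against the rest.
#'
#' @param pred,truth Integer label vectors (0-based), equal length.
#' @param n_classes Number of classes.
#' @return Tibble with one row per class: `class`, `tp`, `tn`, `fp`, `fn`;
#'   the total number of predictions is in the `"N"` attribute.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1), 2)
confusion_counts <- function(pred, truth, n_classes) {
  if (length(pred) != length(truth)) {
    stop_validation("pred and truth must have the same length")
  }
  if (any(pred < 0 | pred >= n_classes) || any(truth < 0 | truth >= n_classes)) {
    stop_validation("labels must lie in [0, n_classes)")
  }
  N <- length(pred)
  rows <- lapply(seq_len(n_classes) - 1L, function(k) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    tibble::tibble(class = k, tp = tp, tn = N - tp - fp - fn, fp = fp, fn = fn)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "N") <- N
  out
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("zero denominator in %s; reporting 0", what), call. = FALSE)
    return(0)
  }
  num / den
}

#' F1 score from precision and recall
#'
#' `F1 = 2 * precision * recall / (precision + recall)`, with the convention
#' that F1 is 0 when precision + recall is 0. Units (fractions or
#' percentages) are preserved.
#'
#' @param precision,recall Numeric scalars or vectors.
#' @return F1 in the same units as the inputs.
#' @export
#' @examples
#' f1_score(71.95, 70.67)
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Classification metrics from confusion counts
#'
#' For two classes, accuracy, precision, recall and F1 are the standard
#' binary formulas with class 1 as the positive class. For more classes,
#' accuracy is the exact-match fraction and precision/recall/F1 are averaged
#' over the per-class one-vs-rest values: unweighted (`"macro"`, default) or
#' pooled over counts (`"micro"`). All values are reported as percentages
#' rounded to 2 decimals.
#'
#' @param counts Result of [confusion_counts()].
#' @param average `"macro"` or `"micro"` (multiclass only).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `average`.
#' @export
metrics_from_counts <- function(counts, average = c("macro", "micro")) {
  average <- match.arg(average)
  N <- attr(counts, "N") %||% (counts$tp[1] + counts$tn[1] + counts$fp[1] + counts$fn[1])
  if (is.null(N) || N == 0) stop_validation("counts cover no predictions")
  n_classes <- nrow(counts)
  if (n_classes == 2L) {
    pos <- counts[counts$class == 1L, ]
    acc <- (pos$tp + pos$tn) / N
    prec <- safe_ratio(pos$tp, pos$tp + pos$fp, "precision")
    rec <- safe_ratio(pos$tp, pos$tp + pos$fn, "recall")
    avg <- "binary"
  } else {
    acc <- sum(counts$tp) / N
    if (average == "macro") {
      precs <- mapply(safe_ratio, counts$tp, counts$tp + counts$fp,
                      MoreArgs = list(what = "precision"))
      recs <- mapply(safe_ratio, counts$tp, counts$tp + counts$fn,
                     MoreArgs = list(what = "recall"))
      prec <- mean(precs)
      rec <- mean(recs)
    } else {
      prec <- safe_ratio(sum(counts$tp), sum(counts$tp) + sum(counts$fp), "precision")
      rec <- safe_ratio(sum(counts$tp), sum(counts$tp) + sum(counts$fn), "recall")
    }
    avg <- average
  }
  tibble::tibble(accuracy = round(100 * acc, 2),
                 precision = round(100 * prec, 2),
                 recall = round(100 * rec, 2),
                 f1 = round(100 * f1_score(prec, rec), 2),
                 average = avg)
}
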