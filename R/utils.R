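# Internal helpers: argument checking and classed conditions.

abort_medtext <- function(msg, class) {
  rlang::abort(msg, class = c(class, "medtext_error"))
}

stop_validation <- function(msg) abort_medtext(msg, "medtext_validation_error")
stop_usage <- function(msg) abort_medtext(msg, "medtext_usage_error")
stop_io <- function(msg) abort_medtext(msg, "medtext_io_error")

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_validation(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_validation(sprintf("`%s` must be a numeric matrix", name))
  }
  invisible(x)
}

# Derive a reproducible child seed from a base seed and a stream label.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(stream))) {
    s <- (s * 31 + ch) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
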