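#' Elementwise activation functions
#'
#' The activations used across both architectures: `relu`, `sigmoid`
#' (`1/(1+e^-z)`), `softplus` (`log(1+e^z)`, computed stably), `hard_sigmoid`
#' (`clip(0.2 z + 0.5, 0, 1)`), `tanh` and `linear`.
#'
#' @param name Activation name.
#' @param z Numeric vector or matrix.
#' @return Transformed values, same shape as `z`.
#' @export
#' @examples
#' apply_activation("sigmoid", 0)
#' apply_activation("softplus", 0)  # log(2)
apply_activation <- function(name, z) {
  fn <- activation_fn(name)
  fn(z)
}

activation_fn <- function(name) {
  switch(name,
    relu = function(z) pmax(z, 0),
    sigmoid = function(z) 1 / (1 + exp(-z)),
    softplus = function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30)))),
    hard_sigmoid = function(z) pmin(pmax(0.2 * z + 0.5, 0), 1),
    tanh = tanh,
    linear = identity,
    stop_usage(sprintf("unknown activation '%s'", name))
  )
}

# Derivative as a function of the pre-activation z and the activation a = f(z).
activation_grad <- function(name) {
  switch(name,
    relu = function(z, a) (z > 0) * 1,
    sigmoid = function(z, a) a * (1 - a),   # sigma' = sigma (1 - sigma)
    softplus = function(z, a) 1 / (1 + exp(-z)),
    hard_sigmoid = function(z, a) (z > -2.5 & z < 2.5) * 0.2,
    tanh = function(z, a) 1 - a^2,
    linear = function(z, a) 1,
    stop_usage(sprintf("unknown activation '%s'", name))
  )
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}
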