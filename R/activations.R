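#' The activation-function pool
#'
#' Eleven scalar activation functions available to hidden nodes during
#' topology evolution. Each is identified by a lowercase name; hidden nodes
#' carry one of these names and may have it swapped by the change-activation
#' mutation. The output node is always `"sigmoid"` so that the network emits
#' a probability.
#'
#' @return Character vector of the 11 activation names.
#' @examples
#' activation_pool()
#' @export
activation_pool <- function() {
  c("linear", "binary_step", "sin", "cosine", "sigmoid", "gaussian",
    "tanh", "inverse", "absolute", "relu", "squared")
}

#' Apply an activation function
#'
#' Vectorised over `x`. `binary_step` returns 1 for `x >= 0` and 0 otherwise;
#' `gaussian` is `exp(-x^2)`; `inverse` is `-x`; `squared` is `x^2`; the rest
#' are the usual definitions.
#'
#' @param kind One of [activation_pool()].
#' @param x Numeric vector of pre-activations (finite).
#' @return Numeric vector, same length as `x`.
#' @examples
#' apply_activation("sigmoid", 0)   # 0.5
#' apply_activation("gaussian", 1)  # exp(-1)
#' @export
apply_activation <- function(kind, x) {
  switch(kind,
    linear      = x,
    binary_step = as.numeric(x >= 0),
    sin         = sin(x),
    cosine      = cos(x),
    sigmoid     = 1 / (1 + exp(-x)),
    gaussian    = exp(-x^2),
    tanh        = tanh(x),
    inverse     = -x,
    absolute    = abs(x),
    relu        = pmax(x, 0),
    squared     = x^2,
    stop("unknown activation kind: ", kind, call. = FALSE)
  )
}

# Integer-coded dispatch used by the compiled forward pass; order matches
# activation_pool().
act_id <- function(kind) {
  id <- match(kind, activation_pool())
  if (anyNA(id)) stop("unknown activation kind: ",
                      paste(kind[is.na(id)], collapse = ", "), call. = FALSE)
  id
}

apply_activation_id <- function(id, x) {
  apply_activation(activation_pool()[id], x)
}
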