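#' Standardize the feature columns of a split
#'
#' Centers and scales every feature column of the train, validation and
#' test partitions using the training partition's means and standard
#' deviations only, so no information leaks from held-out rows. Shared
#' evaluation weights of order one then produce pre-activations of order
#' one instead of saturating the sigmoid on raw temperatures.
#'
#' @param split An `mwr_split` from [split_mwr()].
#' @param label_col Label column left untouched.
#' @return The split with standardized features; the training centers and
#'   scales are attached as attributes `center` and `scale`.
#' @export
standardize_split <- function(split, label_col = "risk") {
  feats <- setdiff(names(split$train), label_col)
  ctr <- vapply(split$train[feats], mean, numeric(1))
  scl <- vapply(split$train[feats], stats::sd, numeric(1))
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  out <- lapply(split, function(d) {
    d[feats] <- sweep(sweep(as.data.frame(d[feats]), 2, ctr), 2, scl, "/")
    d
  })
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  class(out) <- class(split)
  out
}
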