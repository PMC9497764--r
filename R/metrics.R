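#' Classification report for a binary risk model
#'
#' Thresholds the predicted probabilities (`>= threshold` predicts high
#' risk) and reports precision, recall and F1 for the positive (high-risk)
#' class, accuracy, G-mean, the confusion matrix, and — when a genome is
#' supplied — its enabled-connection count.
#'
#' @param labels Binary 0/1 labels (both classes present).
#' @param probabilities Predicted probabilities, same length.
#' @param threshold Decision threshold (default 0.5; ties predict
#'   positive).
#' @param genome Optional `wann_genome` whose connection count to report.
#' @param n_connections Optional connection count when no genome applies
#'   (e.g. a cascade network).
#' @return An `mwr_report` list: `f1`, `accuracy`, `precision`, `recall`,
#'   `gmean`, `n_connections`, `confusion` (tp, fp, tn, fn).
#' @export
classification_report <- function(labels, probabilities, threshold = 0.5,
                                  genome = NULL, n_connections = NA_integer_) {
  if (length(labels) != length(probabilities)) {
    stop("labels and probabilities must have equal length")
  }
  if (length(unique(labels)) < 2) {
    stop("metrics undefined: labels contain a single class")
  }
  pred <- as.numeric(probabilities >= threshold)
  tp <- sum(labels == 1 & pred == 1)
  fp <- sum(labels == 0 & pred == 1)
  tn <- sum(labels == 0 & pred == 0)
  fn <- sum(labels == 1 & pred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  if (!is.null(genome)) n_connections <- count_connections(genome)
  structure(list(
    f1 = f1, accuracy = (tp + tn) / length(labels),
    precision = precision, recall = recall,
    gmean = sqrt(recall * (tn / (tn + fp))),
    n_connections = as.integer(n_connections),
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)
  ), class = "mwr_report")
}

#' @export
print.mwr_report <- function(x, ...) {
  cat(sprintf("<mwr_report> F1 %.4f | accuracy %.4f | precision %.4f | recall %.4f | G-mean %.4f | connections %s\n",
              x$f1, x$accuracy, x$precision, x$recall, x$gmean,
              ifelse(is.na(x$n_connections), "-", x$n_connections)))
  invisible(x)
}

#' Paired comparison of two models' per-sample errors
#'
#' Two-sided paired t-test on the per-sample absolute errors of two models
#' evaluated on the same test rows in the same order. Identical error
#' sequences (zero-variance, zero-mean differences) return `p = 1` by
#' convention; zero-variance non-zero differences return `p = 0`.
#'
#' @param errors_a,errors_b Per-sample absolute errors, equal length >= 2.
#' @return List with `statistic` (t), `p_value`, and `df`.
#' @export
paired_comparison_test <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b) || length(errors_a) < 2) {
    stop("error sequences must have equal length >= 2")
  }
  d <- errors_a - errors_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(statistic = 0, p_value = 1, df = length(d) - 1L))
    }
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0,
                df = length(d) - 1L))
  }
  tt <- stats::t.test(errors_a, errors_b, paired = TRUE,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Mean element-wise output difference between two models
#'
#' Mean and sample standard deviation (n-1 denominator) of the absolute
#' element-wise differences between two models' outputs on the same rows.
#'
#' @param outputs_a,outputs_b Numeric vectors, equal length.
#' @return List with `mean` and `sd`.
#' @export
mean_output_difference <- function(outputs_a, outputs_b) {
  if (length(outputs_a) != length(outputs_b)) {
    stop("output vectors must have equal length")
  }
  d <- abs(outputs_a - outputs_b)
  list(mean = mean(d), sd = stats::sd(d))
}

#' Summarize metrics across seeds
#'
#' Per-metric sample mean and standard deviation (n-1 denominator) over
#' repeated runs with different seeds.
#'
#' @param runs Data frame with one row per run and one numeric column per
#'   metric (a `seed` column, if present, is ignored).
#' @return Tibble with columns `metric`, `mean`, `sd`.
#' @export
multi_seed_summary <- function(runs) {
  runs <- as.data.frame(runs)
  runs <- runs[setdiff(names(runs), "seed")]
  if (nrow(runs) < 2) stop("need at least 2 runs to summarize")
  tibble::tibble(
    metric = names(runs),
    mean = unname(vapply(runs, mean, numeric(1))),
    sd = unname(vapply(runs, stats::sd, numeric(1)))
  )
}
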