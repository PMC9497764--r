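#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a topology search
#'
#' @param x A `wann_search`.
#' @param ... Unused.
#' @return The per-generation history tibble (generation, best_mean_perf,
#'   best_best_perf, min_connections, best_val_perf).
#' @method tidy wann_search
#' @export
tidy.wann_search <- function(x, ...) x$history

#' @method glance wann_search
#' @export
glance.wann_search <- function(x, ...) {
  tibble::tibble(
    generations = nrow(x$history),
    best_val_perf = x$best_val_perf,
    connections = if (is.null(x$best_genome)) NA_integer_ else count_connections(x$best_genome),
    hidden_nodes = if (is.null(x$best_genome)) NA_integer_ else
      sum(x$best_genome$nodes$role == "hidden")
  )
}

#' Tidy a weight-training run
#'
#' @param x A `wann_fit`.
#' @param ... Unused.
#' @return The per-evaluation history tibble (evaluation, train_loss,
#'   val_loss, train_acc, val_acc).
#' @method tidy wann_fit
#' @export
tidy.wann_fit <- function(x, ...) x$history

#' @method glance wann_fit
#' @export
glance.wann_fit <- function(x, ...) {
  tibble::tibble(
    evaluations = x$evaluations,
    scan_weight = x$scan_weight,
    best_val_loss = x$best_val_loss,
    restarts = nrow(x$restarts),
    connections = count_connections(x$genome)
  )
}

#' Tidy a cascade-correlation run
#'
#' @param x A `ccnn_fit`.
#' @param ... Unused.
#' @return The per-iteration history tibble (iteration, train_loss,
#'   val_loss, gmean, connections).
#' @method tidy ccnn_fit
#' @export
tidy.ccnn_fit <- function(x, ...) x$history

#' @method glance ccnn_fit
#' @export
glance.ccnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    hidden_units = length(x$network$hidden),
    connections = last$connections,
    val_loss = last$val_loss,
    gmean = last$gmean
  )
}

#' @method tidy mwr_report
#' @export
tidy.mwr_report <- function(x, ...) {
  tibble::tibble(f1 = x$f1, accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, gmean = x$gmean,
                 n_connections = x$n_connections,
                 tp = x$confusion[["tp"]], fp = x$confusion[["fp"]],
                 tn = x$confusion[["tn"]], fn = x$confusion[["fn"]])
}

#' Plot search progress
#'
#' Best mean and best single shared-weight G-mean per generation, with the
#' minimum connection count on a second panel.
#'
#' @param object A `wann_search`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wann_search
#' @export
autoplot.wann_search <- function(object, ...) {
  h <- object$history
  long <- tibble::tibble(
    generation = rep(h$generation, 3),
    metric = rep(c("best mean G-mean", "best single-weight G-mean",
                   "best validation G-mean"), each = nrow(h)),
    value = c(h$best_mean_perf, h$best_best_perf, h$best_val_perf)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "G-mean", colour = NULL,
                  title = "Weight-agnostic topology search") +
    ggplot2::theme_minimal()
}

#' Plot weight-training curves
#'
#' Cross-entropy loss and accuracy on the training and validation sets
#' across objective evaluations.
#'
#' @param object A `wann_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wann_fit
#' @export
autoplot.wann_fit <- function(object, ...) {
  h <- object$history
  long <- tibble::tibble(
    evaluation = rep(h$evaluation, 4),
    series = rep(c("train loss", "validation loss",
                   "train accuracy", "validation accuracy"), each = nrow(h)),
    panel = rep(c("cross-entropy", "cross-entropy", "accuracy", "accuracy"),
                each = nrow(h)),
    value = c(h$train_loss, h$val_loss, h$train_acc, h$val_acc)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$evaluation, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "objective evaluation", y = NULL, colour = NULL,
                  title = "BIPOP-CMA-ES weight training") +
    ggplot2::theme_minimal()
}

#' Plot cascade growth curves
#'
#' Losses and validation G-mean as hidden units are inserted.
#'
#' @param object A `ccnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ccnn_fit
#' @export
autoplot.ccnn_fit <- function(object, ...) {
  h <- object$history
  long <- tibble::tibble(
    iteration = rep(h$iteration, 3),
    series = rep(c("train loss", "validation loss", "validation G-mean"),
                 each = nrow(h)),
    value = c(h$train_loss, h$val_loss, h$gmean)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "hidden units inserted", y = NULL, colour = NULL,
                  title = "Cascade-correlation growth") +
    ggplot2::theme_minimal()
}
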