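#' Configuration for the cascade-correlation baseline
#'
#' Defaults follow the reference protocol for the 44-feature MWR task: a
#' 30-candidate pool, stochastic gradient steps at learning rate `5e-6`,
#' Gaussian weight initialization with standard deviation 0.5 and zero
#' biases, batch normalization plus dropout (rate 0.5) after each candidate
#' during training, and early stopping with a patience of five iterations.
#' On small rescaled tasks a larger `learning_rate` is appropriate (the
#' losses here are mean-scaled).
#'
#' @param pool_size Candidates trained per insertion.
#' @param learning_rate Step size for output-layer descent and candidate
#'   ascent.
#' @param init_std Std. dev. of Gaussian weight initialization.
#' @param dropout_rate Dropout probability applied to candidate outputs
#'   during training only.
#' @param patience Iterations without validation-loss improvement before
#'   stopping.
#' @param max_hidden Maximum hidden units to insert.
#' @param candidate_epochs,output_epochs Gradient steps per phase.
#' @param seed Optional integer seed.
#' @return A `ccnn_config` list.
#' @export
ccnn_config <- function(pool_size = 30L, learning_rate = 5e-6,
                        init_std = 0.5, dropout_rate = 0.5,
                        patience = 5L, max_hidden = 20L,
                        candidate_epochs = 200L, output_epochs = 200L,
                        seed = NULL) {
  stopifnot(pool_size >= 1, learning_rate > 0, init_std > 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(
    pool_size = as.integer(pool_size), learning_rate = learning_rate,
    init_std = init_std, dropout_rate = dropout_rate,
    patience = as.integer(patience), max_hidden = as.integer(max_hidden),
    candidate_epochs = as.integer(candidate_epochs),
    output_epochs = as.integer(output_epochs), seed = seed
  ), class = "ccnn_config")
}

sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

# Outputs of all frozen hidden units, each fed by the inputs plus every
# earlier unit, normalized with the statistics frozen at insertion time.
ccnn_hidden_matrix <- function(network, X) {
  k <- length(network$hidden)
  H <- matrix(0, nrow = nrow(X), ncol = k)
  Z <- X
  for (i in seq_len(k)) {
    u <- network$hidden[[i]]
    a <- sigmoid(drop(Z %*% u$w) + u$b)
    H[, i] <- (a - u$bn_mean) / u$bn_sd
    Z <- cbind(Z, H[, i])
  }
  H
}

ccnn_forward <- function(network, X) {
  Z <- if (length(network$hidden)) cbind(X, ccnn_hidden_matrix(network, X)) else X
  sigmoid(drop(Z %*% network$out_w) + network$out_b)
}

#' @export
predict.ccnn_network <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$n_inputs)
  ccnn_forward(object, X)
}

# Full-batch gradient descent on mean cross-entropy for the output unit.
train_output_layer <- function(network, X, y, config) {
  Z <- if (length(network$hidden)) cbind(X, ccnn_hidden_matrix(network, X)) else X
  w <- network$out_w; b <- network$out_b
  n <- nrow(Z)
  for (e in seq_len(config$output_epochs)) {
    p <- sigmoid(drop(Z %*% w) + b)
    g <- p - y
    w <- w - config$learning_rate * drop(crossprod(Z, g)) / n
    b <- b - config$learning_rate * mean(g)
  }
  network$out_w <- w; network$out_b <- b
  network
}

#' Candidate correlation score
#'
#' Magnitude of the centered covariance sum between a candidate unit's
#' outputs and the current network's residual errors,
#' `|sum((v - mean(v)) * (e - mean(e)))|`. A constant candidate scores 0.
#'
#' @param candidate_outputs Candidate unit outputs `v`.
#' @param residual_errors Residuals `e` of the current network, same length.
#' @return Non-negative score.
#' @examples
#' candidate_score(c(1, 2, 3), c(0.1, -0.2, 0.4))  # 0.3
#' @export
candidate_score <- function(candidate_outputs, residual_errors) {
  v <- candidate_outputs; e <- residual_errors
  if (length(v) != length(e) || length(v) < 2) {
    stop("candidate outputs and residuals must have equal length >= 2")
  }
  abs(sum((v - mean(v)) * (e - mean(e))))
}

new_candidate <- function(n_in, config) {
  list(w = stats::rnorm(n_in, 0, config$init_std), b = 0)
}

# Candidate unit output on design matrix Z with given batch-norm stats.
candidate_output <- function(cand, Z, bn = NULL) {
  a <- sigmoid(drop(Z %*% cand$w) + cand$b)
  if (is.null(bn)) {
    mu <- mean(a); sd_ <- stats::sd(a)
    if (!is.finite(sd_) || sd_ < 1e-8) sd_ <- 1e-8
    bn <- c(mu, sd_)
  }
  list(v = (a - bn[1]) / bn[2], bn = bn, a = a)
}

#' Train a pool of candidate hidden units and pick the winner
#'
#' Each candidate is a sigmoid unit over the inputs plus all frozen hidden
#' units, followed by batch normalization and dropout (training only). It is
#' trained by gradient ascent on [candidate_score()] against the frozen
#' network's training residuals, stopping early when the score plateaus
#' (relative change below `1e-4` for 10 epochs). The winner is the candidate
#' with the highest validation score, its batch-normalization statistics
#' frozen at the training-set values.
#'
#' @param network Current `ccnn_network`.
#' @param pool Optional list of candidates (`w`, `b`); by default
#'   `config$pool_size` fresh Gaussian-initialized candidates.
#' @param train,validation Data frames with features and a binary label
#'   column.
#' @param config A [ccnn_config()].
#' @param label_col Label column name.
#' @return The winning candidate: list `w`, `b`, `bn_mean`, `bn_sd`,
#'   `val_score`.
#' @export
train_candidates <- function(network, pool = NULL, train, validation,
                             config = ccnn_config(), label_col = "risk") {
  tr <- split_xy(train, label_col)
  va <- split_xy(validation, label_col)
  Ztr <- if (length(network$hidden)) cbind(tr$X, ccnn_hidden_matrix(network, tr$X)) else tr$X
  Zva <- if (length(network$hidden)) cbind(va$X, ccnn_hidden_matrix(network, va$X)) else va$X
  e_tr <- tr$y - ccnn_forward(network, tr$X)
  e_va <- va$y - ccnn_forward(network, va$X)
  eh_tr <- e_tr - mean(e_tr)
  n <- nrow(Ztr)
  if (is.null(pool)) {
    pool <- lapply(seq_len(config$pool_size), function(i)
      new_candidate(ncol(Ztr), config))
  }
  keep <- 1 - config$dropout_rate
  best <- NULL
  for (cand in pool) {
    plateau <- 0L; last_score <- NA_real_
    for (ep in seq_len(config$candidate_epochs)) {
      co <- candidate_output(cand, Ztr)
      mask <- (stats::runif(n) < keep) / keep
      vd <- co$v * mask
      C <- sum(vd * eh_tr)
      deriv <- co$a * (1 - co$a)
      gw <- sign(C) * drop(crossprod(Ztr, eh_tr * mask * deriv / co$bn[2])) / n
      gb <- sign(C) * sum(eh_tr * mask * deriv / co$bn[2]) / n
      cand$w <- cand$w + config$learning_rate * gw
      cand$b <- cand$b + config$learning_rate * gb
      s <- abs(sum(co$v * eh_tr))  # dropout-free score this epoch
      if (is.finite(last_score) &&
          abs(s - last_score) <= 1e-4 * max(abs(last_score), 1e-12)) {
        plateau <- plateau + 1L
        if (plateau >= 10L) break
      } else plateau <- 0L
      last_score <- s
    }
    co_tr <- candidate_output(cand, Ztr)
    co_va <- candidate_output(cand, Zva, bn = co_tr$bn)
    vs <- candidate_score(co_va$v, e_va)
    if (is.null(best) || vs > best$val_score) {
      best <- list(w = cand$w, b = cand$b, bn_mean = co_tr$bn[1],
                   bn_sd = co_tr$bn[2], val_score = vs)
    }
  }
  best
}

#' Connection count of a grown cascade network
#'
#' `d` input-to-output links, plus `d + i` incoming links for the `i`-th
#' inserted unit (`i = 0..k-1`), plus `k` hidden-to-output links. Bias terms
#' are not counted.
#'
#' @param d Number of inputs.
#' @param k Number of inserted hidden units.
#' @return Integer connection count.
#' @export
ccnn_connection_count <- function(d, k) {
  if (k == 0) return(as.integer(d))
  as.integer(d + sum(d + (seq_len(k) - 1)) + k)
}

#' Train a cascade-correlation network
#'
#' Grows the network one hidden unit at a time: (a) train the sigmoid output
#' unit on cross-entropy by gradient descent, (b) train a pool of candidate
#' units against the residuals, (c) insert the best candidate with its
#' incoming weights frozen, (d) reinitialize the output weights and repeat.
#' Stops when the validation loss has not improved for `patience`
#' insertions or `max_hidden` is reached.
#'
#' @param train,validation Data frames with feature columns and a binary
#'   label column (both classes present).
#' @param config A [ccnn_config()].
#' @param label_col Label column name.
#' @return A `ccnn_fit` object: `network` (a `ccnn_network`), `history`
#'   (tibble: iteration, train_loss, val_loss, gmean, connections), and
#'   `config`.
#' @export
train_ccnn <- function(train, validation, config = ccnn_config(),
                       label_col = "risk") {
  if (!is.null(config$seed)) set.seed(config$seed)
  tr <- split_xy(train, label_col)
  va <- split_xy(validation, label_col)
  if (length(unique(tr$y)) < 2 || length(unique(va$y)) < 2) {
    stop("G-mean undefined: labels contain a single class")
  }
  d <- ncol(tr$X)
  network <- structure(list(
    n_inputs = d, hidden = list(),
    out_w = stats::rnorm(d, 0, config$init_std), out_b = 0
  ), class = "ccnn_network")

  hist <- list()
  record <- function(iter) {
    pt <- ccnn_forward(network, tr$X)
    pv <- ccnn_forward(network, va$X)
    tibble::tibble(
      iteration = iter,
      train_loss = cross_entropy(tr$y, pt),
      val_loss = cross_entropy(va$y, pv),
      gmean = gmean_score(va$y, as.numeric(pv >= 0.5)),
      connections = ccnn_connection_count(d, length(network$hidden))
    )
  }

  network <- train_output_layer(network, tr$X, tr$y, config)
  hist[[1]] <- record(0L)
  best_loss <- hist[[1]]$val_loss
  stagnant <- 0L

  for (k in seq_len(config$max_hidden)) {
    winner <- train_candidates(network, pool = NULL,
                               train = train, validation = validation,
                               config = config, label_col = label_col)
    winner$val_score <- NULL
    network$hidden[[k]] <- winner
    network$out_w <- stats::rnorm(d + k, 0, config$init_std)
    network$out_b <- 0
    network <- train_output_layer(network, tr$X, tr$y, config)
    hist[[k + 1]] <- record(k)
    if (hist[[k + 1]]$val_loss < best_loss) {
      best_loss <- hist[[k + 1]]$val_loss
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= config$patience) break
    }
  }

  structure(list(network = network, history = dplyr::bind_rows(hist),
                 config = config), class = "ccnn_fit")
}

#' Read and write cascade networks as JSON
#'
#' Same structured-text container style as [write_genome()]: hidden units
#' are stored with their frozen incoming weights, bias and normalization
#' statistics under role `"hidden"`, the output unit under role
#' `"output"`. Full-precision numbers make the round trip exact.
#'
#' @param network A `ccnn_network`.
#' @param path File path.
#' @return `read_ccnn` returns the network; `write_ccnn` returns `path`
#'   invisibly.
#' @export
write_ccnn <- function(network, path) {
  obj <- list(
    n_inputs = network$n_inputs,
    hidden = lapply(network$hidden, function(u) {
      list(role = "hidden", w = u$w, b = u$b,
           bn_mean = u$bn_mean, bn_sd = u$bn_sd)
    }),
    output = list(role = "output", w = network$out_w, b = network$out_b)
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ccnn
#' @export
read_ccnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  hidden <- lapply(obj$hidden, function(u) {
    list(w = as.numeric(unlist(u$w)), b = as.numeric(u$b),
         bn_mean = as.numeric(u$bn_mean), bn_sd = as.numeric(u$bn_sd))
  })
  structure(list(
    n_inputs = as.integer(obj$n_inputs), hidden = hidden,
    out_w = as.numeric(unlist(obj$output$w)), out_b = as.numeric(obj$output$b)
  ), class = "ccnn_network")
}

#' @export
predict.ccnn_fit <- function(object, newdata, ...) {
  predict(object$network, newdata, ...)
}

#' @export
print.ccnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<ccnn_fit> %d hidden unit(s), %d connection(s); validation loss %.4f, G-mean %.4f\n",
              length(x$network$hidden), last$connections, last$val_loss, last$gmean))
  invisible(x)
}
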