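#' Mean binary cross-entropy
#'
#' Probabilities are clipped to `[1e-12, 1 - 1e-12]` before taking logs.
#'
#' @param labels Binary 0/1 vector.
#' @param probabilities Predicted probabilities, same length.
#' @return Mean of `-(y*log(p) + (1-y)*log(1-p))`.
#' @examples
#' cross_entropy(1, 0.5)  # log(2)
#' @export
cross_entropy <- function(labels, probabilities) {
  if (length(labels) != length(probabilities)) {
    stop("labels and probabilities must have equal length")
  }
  eps <- 1e-12
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  y <- as.numeric(labels)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Linear scan for the best initial shared weight
#'
#' Evaluates the genome's training cross-entropy at `n_points` equally
#' spaced shared weights in `[lo, hi]` and returns the argmin, breaking ties
#' toward the smallest absolute weight, then the smallest weight.
#'
#' @param genome A `wann_genome`.
#' @param features,labels Training rows and binary labels.
#' @param lo,hi Scan interval (default -2 to 2).
#' @param n_points Grid size (default 41, i.e. step 0.1).
#' @return The best scalar shared weight; the full grid is attached as
#'   attribute `"scan"` (tibble: weight, loss).
#' @export
scan_shared_weight <- function(genome, features, labels, lo = -2, hi = 2,
                               n_points = 41L) {
  stopifnot(n_points >= 2, lo < hi)
  X <- as_feature_matrix(features, genome$n_inputs)
  plan <- compile_genome(genome)
  grid <- seq(lo, hi, length.out = n_points)
  losses <- vapply(grid, function(w) {
    cross_entropy(labels, forward_compiled(plan, X, w))
  }, numeric(1))
  best <- which(losses == min(losses))
  best <- best[order(abs(grid[best]), grid[best])][1]
  out <- grid[best]
  attr(out, "scan") <- tibble::tibble(weight = grid, loss = losses)
  out
}

# Canonical CMA-ES strategy parameters for dimension n and offspring count
# lambda (weighted mu/mu_w recombination, cumulative step-size adaptation,
# rank-one + rank-mu covariance update).
cmaes_params <- function(n, lambda) {
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  list(
    mu = mu, weights = w, mueff = mueff,
    cc = (4 + mueff / n) / (n + 4 + 2 * mueff / n),
    cs = (mueff + 2) / (n + mueff + 5),
    c1 = 2 / ((n + 1.3)^2 + mueff),
    cmu = min(1 - 2 / ((n + 1.3)^2 + mueff),
              2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff)),
    damps = 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) +
      (mueff + 2) / (n + mueff + 5),
    chiN = sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))
  )
}

#' Covariance matrix adaptation evolution strategy
#'
#' Derivative-free minimization: each generation samples `lambda` offspring
#' from an adaptive multivariate Gaussian, ranks them by the objective,
#' recombines the best half into a new mean, and updates the two evolution
#' paths, the covariance matrix (rank-one plus rank-mu) and the step size
#' (cumulative step-size adaptation). Strategy constants are the standard
#' defaults.
#'
#' @param objective Function mapping a numeric vector to a finite scalar.
#' @param x0 Starting mean.
#' @param sigma0 Initial step size (> 0).
#' @param lambda Offspring per generation; default `4 + floor(3*log(n))`.
#' @param budget Maximum number of objective evaluations.
#' @param patience Stop after this many consecutive generations without
#'   improvement of the best value (`Inf` disables).
#' @param keep_history Record per-generation progress.
#' @return List: `best_par`, `best_value`, `evaluations`, `stop_reason`
#'   (one of `"budget"`, `"stagnation"`, `"degenerate"`), `history`
#'   (tibble: generation, evaluations, best_value, sigma), and the final
#'   `state` (mean, sigma, covariance, paths, population size, generation).
#' @examples
#' res <- cmaes_minimize(function(x) sum(x^2), c(3, 3), 1, budget = 2000)
#' res$best_value
#' @export
cmaes_minimize <- function(objective, x0, sigma0, lambda = NULL,
                           budget = 10000L, patience = Inf,
                           keep_history = TRUE) {
  n <- length(x0)
  stopifnot(n >= 1, sigma0 > 0)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  lambda <- max(4L, as.integer(lambda))
  par <- cmaes_params(n, lambda)

  m <- as.numeric(x0)
  sigma <- sigma0
  C <- diag(n)
  ps <- numeric(n)
  pc <- numeric(n)
  best_par <- m
  best_value <- Inf
  evals <- 0L
  gen <- 0L
  stagnant <- 0L
  stop_reason <- "budget"
  hist <- list()

  while (evals < budget) {
    gen <- gen + 1L
    C <- (C + t(C)) / 2
    eg <- eigen(C, symmetric = TRUE)
    D2 <- eg$values
    if (min(D2) <= 0 || !all(is.finite(D2)) ||
        max(D2) / max(min(D2), .Machine$double.xmin) > 1e14 ||
        !is.finite(sigma) || sigma < 1e-20 || sigma > 1e20) {
      stop_reason <- "degenerate"
      break
    }
    B <- eg$vectors
    D <- sqrt(D2)
    invsqrtC <- B %*% (t(B) / D)

    k <- min(lambda, budget - evals)
    if (k < lambda) { stop_reason <- "budget"; }
    Z <- matrix(stats::rnorm(n * lambda), nrow = n)
    Y <- B %*% (D * Z)
    X <- m + sigma * Y
    fvals <- numeric(lambda)
    for (i in seq_len(lambda)) {
      if (evals >= budget) { fvals[i] <- Inf; next }
      v <- objective(X[, i])
      evals <- evals + 1L
      if (!is.finite(v)) {
        stop("objective returned a non-finite value at x = (",
             paste(signif(X[, i], 6), collapse = ", "), ")", call. = FALSE)
      }
      fvals[i] <- v
    }
    ord <- order(fvals)
    improved <- fvals[ord[1]] < best_value
    if (improved) {
      best_value <- fvals[ord[1]]
      best_par <- X[, ord[1]]
    }
    sel <- ord[seq_len(par$mu)]
    yw <- drop(Y[, sel, drop = FALSE] %*% par$weights)
    m <- m + sigma * yw

    ps <- (1 - par$cs) * ps +
      sqrt(par$cs * (2 - par$cs) * par$mueff) * drop(invsqrtC %*% yw)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - par$cs)^(2 * gen)) / par$chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - par$cc) * pc +
      hsig * sqrt(par$cc * (2 - par$cc) * par$mueff) * yw
    Ysel <- Y[, sel, drop = FALSE]
    C <- (1 - par$c1 - par$cmu) * C +
      par$c1 * (pc %o% pc + (1 - hsig) * par$cc * (2 - par$cc) * C) +
      par$cmu * (Ysel %*% (par$weights * t(Ysel)))
    sigma <- sigma * exp((par$cs / par$damps) *
                           (sqrt(sum(ps^2)) / par$chiN - 1))

    if (keep_history) {
      hist[[gen]] <- tibble::tibble(generation = gen, evaluations = evals,
                                    best_value = best_value, sigma = sigma)
    }
    stagnant <- if (improved) 0L else stagnant + 1L
    if (stagnant >= patience) { stop_reason <- "stagnation"; break }
  }

  list(
    best_par = best_par, best_value = best_value, evaluations = evals,
    stop_reason = stop_reason,
    history = if (length(hist)) dplyr::bind_rows(hist) else
      tibble::tibble(generation = integer(), evaluations = integer(),
                     best_value = numeric(), sigma = numeric()),
    state = list(mean = m, sigma = sigma, covariance = C, path_sigma = ps,
                 path_c = pc, population_size = lambda, generation = gen,
                 best_solution = list(par = best_par, value = best_value))
  )
}

#' Configuration for BIPOP-style restarted CMA-ES
#'
#' The restart schedule starts at population size 50 and doubles at each
#' restart; the initial shared weight is found by a linear scan over
#' `[-2, 2]`.
#'
#' @param initial_population First restart's offspring count (>= 4).
#' @param max_restarts Restarts after the first run (so up to
#'   `max_restarts + 1` runs).
#' @param scan_lo,scan_hi,scan_points Shared-weight scan grid.
#' @param sigma0 Initial step size.
#' @param max_evaluations Total objective-evaluation budget.
#' @param patience Per-restart stop: optimizer generations without
#'   improvement of the best value.
#' @param seed Optional integer seed.
#' @return A `bipop_config` list.
#' @export
bipop_config <- function(initial_population = 50L, max_restarts = 4L,
                         scan_lo = -2, scan_hi = 2, scan_points = 41L,
                         sigma0 = 0.5, max_evaluations = 10000L,
                         patience = 50L, seed = NULL) {
  stopifnot(initial_population >= 4, scan_lo < scan_hi)
  structure(list(
    initial_population = as.integer(initial_population),
    max_restarts = as.integer(max_restarts),
    scan_lo = scan_lo, scan_hi = scan_hi, scan_points = as.integer(scan_points),
    sigma0 = sigma0, max_evaluations = as.integer(max_evaluations),
    patience = patience, seed = seed
  ), class = "bipop_config")
}

#' Restarted CMA-ES with doubling population size
#'
#' Runs [cmaes_minimize()] with population size `50 * 2^k` at restart `k`,
#' a fresh covariance matrix each restart, and the start point re-centered
#' on the incumbent best solution.
#'
#' @param objective Function to minimize.
#' @param x0 Starting point of the first run.
#' @param config A [bipop_config()].
#' @return List: `best_par`, `best_value`, `evaluations`, and `restarts`, a
#'   tibble with one row per run (restart, lambda, evaluations, best_value,
#'   stop_reason).
#' @export
bipop_optimize <- function(objective, x0, config = bipop_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  best_par <- as.numeric(x0)
  best_value <- Inf
  used <- 0L
  log_rows <- list()
  for (k in 0:config$max_restarts) {
    remaining <- config$max_evaluations - used
    if (remaining < 4) break
    lambda <- config$initial_population * 2L^k
    res <- cmaes_minimize(objective, best_par, config$sigma0,
                          lambda = lambda, budget = remaining,
                          patience = config$patience, keep_history = FALSE)
    used <- used + res$evaluations
    if (res$best_value < best_value) {
      best_value <- res$best_value
      best_par <- res$best_par
    }
    log_rows[[k + 1]] <- tibble::tibble(
      restart = k, lambda = lambda, evaluations = res$evaluations,
      best_value = res$best_value, stop_reason = res$stop_reason)
    if (used >= config$max_evaluations) break
  }
  list(best_par = best_par, best_value = best_value, evaluations = used,
       restarts = dplyr::bind_rows(log_rows))
}

#' Train a WANN topology's weights with BIPOP-CMA-ES
#'
#' Phase two of the pipeline: starting from every weight slot set to the
#' linearly scanned best shared weight, minimize training cross-entropy over
#' the per-connection weight vector. Every objective evaluation also scores
#' the candidate on the validation set; the returned weights are the
#' candidate with the lowest validation cross-entropy seen anywhere in the
#' run (running-minimum model selection).
#'
#' @param genome A `wann_genome` with at least one enabled connection.
#' @param train,validation Data frames with feature columns and a binary
#'   label column.
#' @param config A [bipop_config()].
#' @param label_col Label column name.
#' @return A `wann_fit` object: `genome` (with `$weights` set), `weights`,
#'   `scan_weight`, `best_val_loss`, `evaluations`, `history` (tibble:
#'   evaluation, train_loss, val_loss, train_acc, val_acc), `restarts`.
#' @export
train_wann_weights <- function(genome, train, validation,
                               config = bipop_config(), label_col = "risk") {
  d <- count_connections(genome)
  if (d == 0L) stop("genome has no enabled connections: nothing to train")
  if (!is.null(config$seed)) set.seed(config$seed)
  tr <- split_xy(train, label_col)
  va <- split_xy(validation, label_col)
  plan <- compile_genome(genome)

  w0 <- scan_shared_weight(genome, tr$X, tr$y,
                           lo = config$scan_lo, hi = config$scan_hi,
                           n_points = config$scan_points)
  x0 <- rep(as.numeric(w0), d)

  env <- new.env()
  env$hist <- vector("list", config$max_evaluations + 1L)
  env$i <- 0L
  env$best_val <- Inf
  env$best_w <- x0
  obj <- function(w) {
    pt <- forward_compiled(plan, tr$X, w)
    pv <- forward_compiled(plan, va$X, w)
    tl <- cross_entropy(tr$y, pt)
    vl <- cross_entropy(va$y, pv)
    env$i <- env$i + 1L
    env$hist[[env$i]] <- c(tl, vl,
                           mean((pt >= 0.5) == tr$y),
                           mean((pv >= 0.5) == va$y))
    if (vl < env$best_val) { env$best_val <- vl; env$best_w <- w }
    tl
  }
  obj(x0)  # baseline: the scanned shared weight itself
  inner_cfg <- config
  inner_cfg$seed <- NULL
  inner_cfg$max_evaluations <- config$max_evaluations - 1L
  res <- bipop_optimize(obj, x0, inner_cfg)

  h <- do.call(rbind, env$hist[seq_len(env$i)])
  history <- tibble::tibble(
    evaluation = seq_len(env$i),
    train_loss = h[, 1], val_loss = h[, 2],
    train_acc = h[, 3], val_acc = h[, 4]
  )
  genome$weights <- as.numeric(env$best_w)
  structure(list(
    genome = genome, weights = as.numeric(env$best_w),
    scan_weight = as.numeric(w0), best_val_loss = env$best_val,
    evaluations = env$i, history = history, restarts = res$restarts
  ), class = "wann_fit")
}

#' @export
print.wann_fit <- function(x, ...) {
  cat(sprintf("<wann_fit> %d weight(s); scan start %.3f; best validation loss %.4f after %d evaluation(s)\n",
              length(x$weights), x$scan_weight, x$best_val_loss, x$evaluations))
  invisible(x)
}
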