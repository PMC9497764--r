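#' Configuration for the weight-agnostic topology search
#'
#' Defaults follow the reference search protocol: 200 generations of a
#' 200-genome population, mutation operator probabilities (0.5, 0.25, 0.25)
#' for change-activation / add-node / add-connection, 20% initially active
#' input-to-output connections, tournament size 4, and shared evaluation
#' weights \{-2, -1.5, -1, -0.5, +0.5, +1, +1.5, +2\}.
#'
#' @param generations Number of evolve cycles.
#' @param population_size Genomes per generation.
#' @param p_change_activation,p_add_node,p_add_connection Mutation operator
#'   probabilities; must sum to 1.
#' @param initial_active_fraction Probability that each possible input/bias
#'   to output connection is enabled at initialization.
#' @param tournament_size Members drawn (with replacement) per tournament.
#' @param shared_weights Non-zero scalar weights used for weight-agnostic
#'   evaluation.
#' @param elite_fraction Upper bound on the share of the population carried
#'   over unmutated from the first non-dominated front.
#' @param stagnation Stop early after this many generations without
#'   improvement of the best validation mean performance (`Inf` disables).
#' @param seed Optional integer seed fixing the whole search trajectory.
#' @return A `wann_config` list.
#' @export
wann_config <- function(generations = 200L, population_size = 200L,
                        p_change_activation = 0.5, p_add_node = 0.25,
                        p_add_connection = 0.25,
                        initial_active_fraction = 0.2,
                        tournament_size = 4L,
                        shared_weights = c(-2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2),
                        elite_fraction = 0.2,
                        stagnation = Inf,
                        seed = NULL) {
  p <- c(p_change_activation, p_add_node, p_add_connection)
  if (abs(sum(p) - 1) > 1e-9) stop("mutation probabilities must sum to 1")
  if (length(shared_weights) == 0 || any(shared_weights == 0)) {
    stop("shared_weights must be non-empty and exclude 0")
  }
  structure(list(
    generations = as.integer(generations),
    population_size = as.integer(population_size),
    p_change_activation = p_change_activation,
    p_add_node = p_add_node,
    p_add_connection = p_add_connection,
    initial_active_fraction = initial_active_fraction,
    tournament_size = as.integer(tournament_size),
    shared_weights = shared_weights,
    elite_fraction = elite_fraction,
    stagnation = stagnation,
    seed = seed
  ), class = "wann_config")
}

#' Initialize a population of sparse genomes
#'
#' Each genome has only input, bias and output nodes; every possible
#' input/bias-to-output connection is enabled independently with probability
#' `config$initial_active_fraction`, so populations start sparse.
#'
#' @param config A [wann_config()].
#' @param n_inputs,n_outputs Network interface sizes.
#' @return List of `population_size` genomes.
#' @export
init_population <- function(config, n_inputs, n_outputs = 1L) {
  lapply(seq_len(config$population_size), function(i) {
    g <- minimal_genome(n_inputs, n_outputs)
    srcs <- seq_len(n_inputs + 1L)                       # inputs + bias
    tgts <- n_inputs + 1L + seq_len(n_outputs)           # outputs
    pairs <- expand.grid(source = srcs, target = tgts)
    keep <- stats::runif(nrow(pairs)) < config$initial_active_fraction
    if (any(keep)) {
      sel <- pairs[keep, , drop = FALSE]
      g$connections <- data.frame(
        conn_id = seq_len(nrow(sel)),
        source = as.integer(sel$source), target = as.integer(sel$target),
        enabled = TRUE, weight_slot = NA_integer_
      )
      g <- compact_slots(g)
    }
    g
  })
}

# Enabled-edge descendant set of node `id` (ids, not positions).
reachable_from <- function(conn, id) {
  out <- integer(0)
  frontier <- id
  while (length(frontier)) {
    nxt <- unique(conn$target[conn$source %in% frontier])
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# All (source, target) pairs a new enabled connection may legally join:
# source is input/bias/hidden, target hidden/output, pair not already
# connected (in either direction, enabled or not), and the edge keeps the
# enabled graph acyclic.
valid_new_connections <- function(genome) {
  nd <- genome$nodes
  cn <- genome$connections
  srcs <- nd$node_id[nd$role %in% c("input", "bias", "hidden")]
  tgts <- nd$node_id[nd$role %in% c("hidden", "output")]
  pairs <- expand.grid(source = srcs, target = tgts)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  if (nrow(cn)) {
    key <- paste(cn$source, cn$target)
    rkey <- paste(cn$target, cn$source)
    pk <- paste(pairs$source, pairs$target)
    pairs <- pairs[!(pk %in% key) & !(pk %in% rkey), , drop = FALSE]
  }
  if (!nrow(pairs)) return(pairs)
  en <- cn[cn$enabled, , drop = FALSE]
  ok <- vapply(seq_len(nrow(pairs)), function(i) {
    !(pairs$source[i] %in% reachable_from(en, pairs$target[i]))
  }, logical(1))
  pairs[ok, , drop = FALSE]
}

mutate_add_node <- function(genome) {
  en_idx <- which(genome$connections$enabled)
  if (!length(en_idx)) return(NULL)
  pick <- en_idx[sample.int(length(en_idx), 1L)]
  src <- genome$connections$source[pick]
  tgt <- genome$connections$target[pick]
  new_id <- max(genome$nodes$node_id) + 1L
  act <- sample(activation_pool(), 1L)
  genome$nodes <- rbind(genome$nodes, data.frame(
    node_id = new_id, role = "hidden", activation = act))
  genome$connections$enabled[pick] <- FALSE
  next_cid <- if (nrow(genome$connections)) max(genome$connections$conn_id) + 1L else 1L
  genome$connections <- rbind(genome$connections, data.frame(
    conn_id = c(next_cid, next_cid + 1L),
    source = c(src, new_id), target = c(new_id, tgt),
    enabled = TRUE, weight_slot = NA_integer_))
  compact_slots(genome)
}

mutate_add_connection <- function(genome) {
  pairs <- valid_new_connections(genome)
  if (!nrow(pairs)) return(NULL)
  pick <- pairs[sample.int(nrow(pairs), 1L), ]
  next_cid <- if (nrow(genome$connections)) max(genome$connections$conn_id) + 1L else 1L
  genome$connections <- rbind(genome$connections, data.frame(
    conn_id = next_cid, source = as.integer(pick$source),
    target = as.integer(pick$target), enabled = TRUE,
    weight_slot = NA_integer_))
  compact_slots(genome)
}

mutate_change_activation <- function(genome) {
  hid <- which(genome$nodes$role == "hidden")
  if (!length(hid)) return(NULL)
  pick <- hid[sample.int(length(hid), 1L)]
  current <- genome$nodes$activation[pick]
  genome$nodes$activation[pick] <- sample(setdiff(activation_pool(), current), 1L)
  genome
}

#' Apply one structural mutation to a genome
#'
#' One of three operators, sampled with the configured probabilities:
#' change a hidden node's activation (0.5), insert a node by splitting an
#' enabled connection (0.25; the split connection is disabled, so the
#' enabled count rises by one), or add a new enabled connection between a
#' uniformly chosen valid pair that keeps the graph acyclic (0.25). When the
#' sampled operator is inapplicable the fallback order is add-connection,
#' change-activation, add-node, identity. The input genome is never modified
#' in place; the applied operator is attached as attribute `"mutation"`.
#'
#' @param genome A `wann_genome`.
#' @param config A [wann_config()].
#' @return The mutated genome.
#' @export
mutate_genome <- function(genome, config = wann_config()) {
  u <- stats::runif(1)
  sampled <- if (u < config$p_change_activation) {
    "change_activation"
  } else if (u < config$p_change_activation + config$p_add_node) {
    "add_node"
  } else {
    "add_connection"
  }
  apply_op <- function(op) {
    switch(op,
      change_activation = mutate_change_activation(genome),
      add_node = mutate_add_node(genome),
      add_connection = mutate_add_connection(genome))
  }
  out <- apply_op(sampled)
  applied <- sampled
  if (is.null(out)) {
    for (op in c("add_connection", "change_activation", "add_node")) {
      out <- apply_op(op)
      if (!is.null(out)) { applied <- op; break }
    }
  }
  if (is.null(out)) { out <- genome; applied <- "identity" }
  attr(out, "mutation") <- applied
  attr(out, "sampled_mutation") <- sampled
  out
}

#' Geometric-mean score for binary predictions
#'
#' `sqrt(sensitivity * specificity)` from the confusion matrix, the
#' balanced evaluation metric used to score topologies during the
#' weight-agnostic search (positive class = 1 = high risk).
#'
#' @param labels Binary 0/1 vector containing both classes.
#' @param predictions Binary 0/1 vector of the same length.
#' @return A number in \[0, 1\].
#' @export
gmean_score <- function(labels, predictions) {
  if (length(labels) != length(predictions) || length(labels) == 0) {
    stop("labels and predictions must have equal non-zero length")
  }
  if (length(unique(labels)) < 2) {
    stop("G-mean undefined: labels contain a single class")
  }
  tp <- sum(labels == 1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  sqrt((tp / (tp + fn)) * (tn / (tn + fp)))
}

#' Weight-agnostic fitness of one genome
#'
#' Runs the genome over the feature rows once per shared weight, thresholds
#' the output probability at 0.5 (ties to positive) and scores each run by
#' [gmean_score()].
#'
#' @param genome A `wann_genome`.
#' @param features Matrix/data frame of feature rows.
#' @param labels Binary labels (both classes present).
#' @param shared_weights Scalar weights to substitute, one evaluation each.
#' @return List with `mean_perf` (mean G-mean over the shared weights),
#'   `best_perf` (max), `n_connections`.
#' @export
evaluate_genome <- function(genome, features, labels,
                            shared_weights = wann_config()$shared_weights) {
  X <- as_feature_matrix(features, genome$n_inputs)
  plan <- compile_genome(genome)
  scores <- vapply(shared_weights, function(w) {
    p <- forward_compiled(plan, X, w)
    gmean_score(labels, as.numeric(p >= 0.5))
  }, numeric(1))
  list(mean_perf = mean(scores), best_perf = max(scores),
       n_connections = count_connections(genome))
}

#' NSGA-II ranking of fitness records
#'
#' Fast non-dominated sorting on three objectives — maximize mean shared-
#' weight performance, maximize best shared-weight performance, minimize
#' connection count — followed by per-front crowding distances (boundary
#' points at `Inf`).
#'
#' @param records Data frame with columns `mean_perf`, `best_perf`,
#'   `n_connections` (one row per genome).
#' @return Tibble with `front` (0-based front index) and `crowding`.
#' @export
nsga2_rank <- function(records) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n < 1) stop("need at least one record")
  # minimization orientation
  obj <- cbind(-records$mean_perf, -records$best_perf, records$n_connections)
  front <- integer(n)
  if (n == 1) {
    return(tibble::tibble(front = 0L, crowding = Inf))
  }
  # dominance matrix: dom[i, j] TRUE iff i dominates j
  dom <- matrix(FALSE, n, n)
  for (k in 1:3) {
    le <- outer(obj[, k], obj[, k], `<=`)
    lt <- outer(obj[, k], obj[, k], `<`)
    if (k == 1) { all_le <- le; any_lt <- lt } else {
      all_le <- all_le & le; any_lt <- any_lt | lt
    }
  }
  dom <- all_le & any_lt
  n_dominating <- colSums(dom)
  remaining <- rep(TRUE, n)
  f <- 0L
  while (any(remaining)) {
    members <- which(remaining & n_dominating == 0L)
    front[members] <- f
    remaining[members] <- FALSE
    if (any(remaining)) {
      dec <- colSums(dom[members, , drop = FALSE])
      n_dominating <- n_dominating - dec
      n_dominating[!remaining] <- -1L
    }
    f <- f + 1L
  }
  crowd <- numeric(n)
  for (fi in unique(front)) {
    members <- which(front == fi)
    if (length(members) <= 2) { crowd[members] <- Inf; next }
    d <- numeric(length(members))
    for (k in 1:3) {
      o <- obj[members, k]
      ord <- order(o)
      rng <- o[ord[length(ord)]] - o[ord[1]]
      d[ord[1]] <- Inf
      d[ord[length(ord)]] <- Inf
      if (rng > 0) {
        inner <- 2:(length(ord) - 1)
        d[ord[inner]] <- d[ord[inner]] + (o[ord[inner + 1]] - o[ord[inner - 1]]) / rng
      }
    }
    crowd[members] <- d
  }
  tibble::tibble(front = front, crowding = crowd)
}

tournament_select_index <- function(ranks, size) {
  n <- nrow(ranks)
  cand <- sample.int(n, size, replace = TRUE)
  best <- cand[1]
  for (i in cand[-1]) {
    if (ranks$front[i] < ranks$front[best] ||
        (ranks$front[i] == ranks$front[best] && ranks$crowding[i] > ranks$crowding[best]) ||
        (ranks$front[i] == ranks$front[best] && ranks$crowding[i] == ranks$crowding[best] && i < best)) {
      best <- i
    }
  }
  best
}

#' Tournament selection
#'
#' Draws `size` population members uniformly with replacement; the winner
#' has the lowest front index, ties broken by larger crowding distance, then
#' by lower population index.
#'
#' @param population List of genomes.
#' @param ranks Output of [nsga2_rank()] aligned with `population`.
#' @param size Tournament size.
#' @return The winning genome, with its population index as attribute
#'   `"pop_index"`.
#' @export
tournament_select <- function(population, ranks, size = 4L) {
  if (!length(population)) stop("population is empty")
  i <- tournament_select_index(ranks, size)
  g <- population[[i]]
  attr(g, "pop_index") <- i
  g
}

#' Run the weight-agnostic topology search
#'
#' Evolution loop: evaluate every genome under the shared weights, rank with
#' [nsga2_rank()], carry the first front over unmutated (up to
#' `elite_fraction` of the population), and fill the rest with mutated
#' tournament winners. The returned best genome is the front-0 member with
#' the highest validation mean performance seen at any generation, ties
#' broken by fewer connections.
#'
#' @param train,validation Data frames of feature columns plus a binary
#'   label column.
#' @param config A [wann_config()].
#' @param label_col Name of the label column (0 = low risk, 1 = high risk).
#' @return A `wann_search` object: `best_genome`, `best_val_perf`,
#'   `history` (tibble: generation, best_mean_perf, best_best_perf,
#'   min_connections, best_val_perf), `population`, `records`, `config`,
#'   `feature_names`.
#' @export
run_wann_search <- function(train, validation, config = wann_config(),
                            label_col = "risk") {
  if (!is.null(config$seed)) set.seed(config$seed)
  tr <- split_xy(train, label_col)
  va <- split_xy(validation, label_col)
  pop <- init_population(config, ncol(tr$X), 1L)
  n_elite <- max(1L, min(floor(config$elite_fraction * config$population_size),
                         config$population_size))

  best <- list(genome = NULL, val_perf = -Inf, conn = Inf)
  consider <- function(genome, rec_val) {
    if (rec_val$mean_perf > best$val_perf ||
        (rec_val$mean_perf == best$val_perf && rec_val$n_connections < best$conn)) {
      best <<- list(genome = genome, val_perf = rec_val$mean_perf,
                    conn = rec_val$n_connections)
    }
  }
  eval_pop <- function(pop) {
    lapply(pop, evaluate_genome, features = tr$X, labels = tr$y,
           shared_weights = config$shared_weights)
  }
  records_df <- function(recs) {
    data.frame(mean_perf = vapply(recs, `[[`, numeric(1), "mean_perf"),
               best_perf = vapply(recs, `[[`, numeric(1), "best_perf"),
               n_connections = vapply(recs, `[[`, numeric(1), "n_connections"))
  }

  history <- vector("list", config$generations)
  recs <- eval_pop(pop)
  rdf <- records_df(recs)
  stagnant <- 0L
  g_done <- 0L

  if (config$generations == 0L) {
    ranks <- nsga2_rank(rdf)
    for (i in order(ranks$front)[seq_len(min(n_elite, length(pop)))]) {
      consider(pop[[i]], evaluate_genome(pop[[i]], va$X, va$y, config$shared_weights))
    }
  }

  for (gen in seq_len(config$generations)) {
    ranks <- nsga2_rank(rdf)
    front0 <- which(ranks$front == 0L)
    elite_idx <- front0[order(-ranks$crowding[front0])][seq_len(min(n_elite, length(front0)))]
    prev_best <- best$val_perf
    for (i in elite_idx) {
      consider(pop[[i]], evaluate_genome(pop[[i]], va$X, va$y, config$shared_weights))
    }
    history[[gen]] <- tibble::tibble(
      generation = gen,
      best_mean_perf = max(rdf$mean_perf),
      best_best_perf = max(rdf$best_perf),
      min_connections = min(rdf$n_connections),
      best_val_perf = best$val_perf
    )
    g_done <- gen
    stagnant <- if (best$val_perf > prev_best) 0L else stagnant + 1L
    if (stagnant >= config$stagnation) break
    if (gen == config$generations) break
    offspring <- lapply(seq_len(config$population_size - length(elite_idx)), function(i) {
      parent <- pop[[tournament_select_index(ranks, config$tournament_size)]]
      mutate_genome(parent, config)
    })
    pop <- c(pop[elite_idx], offspring)
    recs <- eval_pop(pop)
    rdf <- records_df(recs)
  }

  structure(list(
    best_genome = best$genome,
    best_val_perf = best$val_perf,
    history = if (g_done) dplyr::bind_rows(history[seq_len(g_done)]) else
      tibble::tibble(generation = integer(), best_mean_perf = numeric(),
                     best_best_perf = numeric(), min_connections = numeric(),
                     best_val_perf = numeric()),
    population = pop,
    records = rdf,
    config = config,
    feature_names = colnames(tr$X)
  ), class = "wann_search")
}

split_xy <- function(data, label_col) {
  data <- as.data.frame(data)
  if (!label_col %in% names(data)) {
    stop("label column '", label_col, "' not found")
  }
  y <- data[[label_col]]
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  X <- as.matrix(data[setdiff(names(data), label_col)])
  storage.mode(X) <- "double"
  list(X = X, y = as.numeric(y))
}

#' @export
print.wann_search <- function(x, ...) {
  cat(sprintf("<wann_search> %d generation(s); best validation G-mean %.4f with %d connection(s)\n",
              nrow(x$history), x$best_val_perf,
              if (is.null(x$best_genome)) NA_integer_ else count_connections(x$best_genome)))
  invisible(x)
}
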