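# Shared fixtures and independent oracles for the test suite.

# Build a genome from explicit node/edge lists. Hidden nodes get ids
# following the input/bias/output block; `edges` is a data frame with
# columns source, target (node ids) and optionally enabled.
make_genome <- function(n_inputs, hidden_activations = character(),
                        edges = NULL, n_outputs = 1L) {
  g <- minimal_genome(n_inputs, n_outputs)
  for (act in hidden_activations) {
    g$nodes <- rbind(g$nodes, data.frame(
      node_id = max(g$nodes$node_id) + 1L, role = "hidden", activation = act))
  }
  if (!is.null(edges)) {
    if (is.null(edges$enabled)) edges$enabled <- TRUE
    g$connections <- data.frame(
      conn_id = seq_len(nrow(edges)),
      source = as.integer(edges$source), target = as.integer(edges$target),
      enabled = as.logical(edges$enabled), weight_slot = NA_integer_)
    g <- wannmwr:::compact_slots(g)
  }
  g
}

# All topological orders of a small DAG by exhaustive recursion;
# independent of the package's Kahn implementation.
all_topo_orders <- function(ids, edges) {
  if (!length(ids)) return(list(integer(0)))
  out <- list()
  for (v in ids) {
    if (!any(edges$target == v & edges$source %in% ids)) {
      rest <- all_topo_orders(setdiff(ids, v),
                              edges[edges$source != v, , drop = FALSE])
      out <- c(out, lapply(rest, function(r) c(v, r)))
    }
  }
  out
}

# Brute-force non-dominated peeling for (max mean, max best, min conn),
# O(n^2) pairwise dominance checks.
bf_pareto_fronts <- function(records) {
  n <- nrow(records)
  dominates <- function(i, j) {
    ge <- records$mean_perf[i] >= records$mean_perf[j] &&
      records$best_perf[i] >= records$best_perf[j] &&
      records$n_connections[i] <= records$n_connections[j]
    gt <- records$mean_perf[i] > records$mean_perf[j] ||
      records$best_perf[i] > records$best_perf[j] ||
      records$n_connections[i] < records$n_connections[j]
    ge && gt
  }
  front <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  f <- 0L
  while (length(remaining)) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(setdiff(remaining, i), function(j) dominates(j, i),
                  logical(1)))
    }, logical(1))]
    front[nd] <- f
    remaining <- setdiff(remaining, nd)
    f <- f + 1L
  }
  front
}

# Two-class task with a planted XOR structure (not linearly separable).
make_xor_task <- function(n, seed) {
  set.seed(seed)
  x1 <- stats::runif(n, -1, 1)
  x2 <- stats::runif(n, -1, 1)
  tibble::tibble(x1 = x1, x2 = x2,
                 risk = as.integer(xor(x1 > 0, x2 > 0)))
}

# Linearly separable two-feature task.
make_separable_task <- function(n, seed) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  tibble::tibble(x1 = stats::rnorm(n, ifelse(y == 1, 1.5, -1.5), 0.5),
                 x2 = stats::rnorm(n, 0, 0.5),
                 risk = y)
}

# Small standardized synthetic split used by several tests.
make_small_split <- function(seed, n = 60) {
  d <- generate_synthetic_mwr(synthetic_config(n_low = n, n_high = n,
                                               seed = seed))
  standardize_split(split_mwr(d, seed = seed))
}

random_dag_genome <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  # ids 1..n_nodes with edges only id_lo -> id_hi: guaranteed acyclic
  n_inputs <- 2L
  g <- minimal_genome(n_inputs)
  extra <- n_nodes - nrow(g$nodes)
  acts <- sample(activation_pool(), max(extra, 0), replace = TRUE)
  g <- make_genome(n_inputs, acts)
  ids <- g$nodes$node_id
  hid <- g$nodes$node_id[g$nodes$role == "hidden"]
  out <- g$nodes$node_id[g$nodes$role == "output"]
  srcs <- c(seq_len(n_inputs + 1L), hid)
  tgts <- c(hid, out)
  e <- expand.grid(source = srcs, target = tgts)
  e <- e[e$source < e$target | (e$source %in% seq_len(n_inputs + 1L) & e$target %in% c(hid, out)), ]
  e <- e[e$source != e$target, ]
  # keep feedforward direction: lower id feeds higher id among hidden
  e <- e[!(e$source %in% hid & e$target %in% hid & e$source >= e$target), ]
  e <- unique(e)
  keep <- stats::runif(nrow(e)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  make_genome(n_inputs, acts, e[keep, , drop = FALSE])
}
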