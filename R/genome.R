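#' Feedforward network genomes
#'
#' A genome is the unit of topology evolution: a feedforward DAG with typed
#' nodes (input, bias, hidden, output) and directed, enable-flagged
#' connections. Each enabled connection owns a slot in a compact weight
#' vector, so the same genome can be evaluated either with one shared scalar
#' weight (weight-agnostic mode) or with a fully trained weight vector.
#'
#' Node ids `1..n_inputs` are the inputs, `n_inputs + 1` is the constant-1
#' bias node, the next `n_outputs` ids are outputs, and hidden nodes are
#' appended as mutation creates them. The single output node's activation is
#' fixed to the logistic sigmoid so the network output is a probability.
#'
#' @param n_inputs Number of input features (44 for MWR temperature rows).
#' @param n_outputs Number of outputs (1 for binary risk).
#' @return A `wann_genome`: list with `nodes` (data frame: `node_id`, `role`,
#'   `activation`), `connections` (data frame: `conn_id`, `source`, `target`,
#'   `enabled`, `weight_slot`), `n_inputs`, `n_outputs`.
#' @examples
#' g <- minimal_genome(4)
#' count_connections(g)
#' @export
minimal_genome <- function(n_inputs, n_outputs = 1L) {
  stopifnot(n_inputs >= 1, n_outputs >= 1)
  n_inputs <- as.integer(n_inputs); n_outputs <- as.integer(n_outputs)
  nodes <- data.frame(
    node_id = seq_len(n_inputs + 1L + n_outputs),
    role = c(rep("input", n_inputs), "bias", rep("output", n_outputs)),
    activation = c(rep("linear", n_inputs + 1L), rep("sigmoid", n_outputs)),
    stringsAsFactors = FALSE
  )
  g <- structure(
    list(nodes = nodes, connections = empty_connections(),
         n_inputs = n_inputs, n_outputs = n_outputs),
    class = "wann_genome"
  )
  g
}

empty_connections <- function() {
  data.frame(conn_id = integer(), source = integer(), target = integer(),
             enabled = logical(), weight_slot = integer())
}

#' @export
print.wann_genome <- function(x, ...) {
  cat(sprintf("<wann_genome> %d inputs, %d output(s), %d hidden node(s), %d enabled connection(s)\n",
              x$n_inputs, x$n_outputs, sum(x$nodes$role == "hidden"),
              count_connections(x)))
  invisible(x)
}

# Reassign weight slots 0..(n_enabled - 1) in connection order; disabled
# connections carry NA.
compact_slots <- function(genome) {
  en <- genome$connections$enabled
  genome$connections$weight_slot <- NA_integer_
  genome$connections$weight_slot[en] <- seq_len(sum(en)) - 1L
  genome
}

#' Count enabled connections
#'
#' The model-size objective used by the multi-objective ranking and reported
#' alongside classification metrics.
#'
#' @param genome A `wann_genome`.
#' @return Integer count of enabled connections.
#' @export
count_connections <- function(genome) {
  sum(genome$connections$enabled)
}

#' Topological node order
#'
#' Kahn's algorithm restricted to enabled connections, breaking ties by
#' ascending `node_id` so the order is unique and reproducible.
#'
#' @param genome A `wann_genome`.
#' @return Integer vector of node ids, every enabled edge's source before its
#'   target.
#' @export
topological_order <- function(genome) {
  ids <- genome$nodes$node_id
  conn <- genome$connections[genome$connections$enabled, , drop = FALSE]
  indeg <- integer(length(ids))
  names(indeg) <- ids
  if (nrow(conn)) {
    tb <- table(conn$target)
    indeg[names(tb)] <- as.integer(tb)
  }
  out <- integer(0)
  remaining <- ids
  while (length(remaining)) {
    ready <- remaining[indeg[as.character(remaining)] == 0L]
    if (!length(ready)) {
      # cycle: name one edge among the stuck nodes
      stuck <- conn[conn$source %in% remaining & conn$target %in% remaining, ]
      stop(sprintf("genome contains a cycle (e.g. edge %d -> %d)",
                   stuck$source[1], stuck$target[1]), call. = FALSE)
    }
    nxt <- min(ready)
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    for (tg in conn$target[conn$source == nxt]) {
      indeg[as.character(tg)] <- indeg[as.character(tg)] - 1L
    }
  }
  out
}

validate_genome <- function(genome) {
  stopifnot(inherits(genome, "wann_genome"))
  nd <- genome$nodes; cn <- genome$connections
  stopifnot(!anyDuplicated(nd$node_id), all(nd$role %in% c("input", "bias", "hidden", "output")))
  stopifnot(all(cn$source %in% nd$node_id), all(cn$target %in% nd$node_id))
  src_role <- nd$role[match(cn$source, nd$node_id)]
  tgt_role <- nd$role[match(cn$target, nd$node_id)]
  if (any(tgt_role %in% c("input", "bias"))) stop("input/bias nodes cannot receive connections")
  if (any(src_role == "output")) stop("output nodes cannot emit connections")
  en <- cn$enabled
  slots <- sort(cn$weight_slot[en])
  if (length(slots) && !identical(slots, seq_len(sum(en)) - 1L)) {
    stop("weight slots are not compact 0..(n_enabled-1)")
  }
  topological_order(genome)  # errors on a cycle
  invisible(TRUE)
}

# Compile a genome into an evaluation plan: nodes to visit (past the
# input/bias block) in topological order, with integer-indexed incoming
# sources and weight slots. Cuts per-forward overhead when the same topology
# is evaluated under many weight vectors.
compile_genome <- function(genome) {
  ord <- topological_order(genome)
  nd <- genome$nodes
  idx <- match(ord, nd$node_id)           # position in node table, topo order
  pos_of_id <- match(nd$node_id, nd$node_id)  # identity; ids are 1..k only at birth
  conn <- genome$connections[genome$connections$enabled, , drop = FALSE]
  eval_nodes <- list()
  for (i in seq_along(ord)) {
    id <- ord[i]
    role <- nd$role[idx[i]]
    if (role %in% c("input", "bias")) next
    inc <- conn[conn$target == id, , drop = FALSE]
    eval_nodes[[length(eval_nodes) + 1L]] <- list(
      col = match(id, nd$node_id),
      sources = match(inc$source, nd$node_id),
      slots = inc$weight_slot + 1L,
      act = act_id(nd$activation[idx[i]]),
      is_output = role == "output"
    )
  }
  list(
    n_nodes = nrow(nd),
    input_cols = match(seq_len(genome$n_inputs), nd$node_id),
    bias_col = match(genome$n_inputs + 1L, nd$node_id),
    output_col = match(nd$node_id[nd$role == "output"][1], nd$node_id),
    eval_nodes = eval_nodes,
    n_slots = count_connections(genome)
  )
}

PREACT_CLAMP <- 1e4

forward_compiled <- function(plan, X, weights) {
  n <- nrow(X)
  w <- if (length(weights) == 1L) rep(weights, plan$n_slots) else weights
  if (length(w) != plan$n_slots) {
    stop(sprintf("weight vector length %d != enabled connection count %d",
                 length(w), plan$n_slots), call. = FALSE)
  }
  V <- matrix(0, nrow = n, ncol = plan$n_nodes)
  V[, plan$input_cols] <- X
  V[, plan$bias_col] <- 1
  for (nd in plan$eval_nodes) {
    pre <- if (length(nd$sources) == 0L) {
      numeric(n)
    } else if (length(nd$sources) == 1L) {
      V[, nd$sources] * w[nd$slots]
    } else {
      drop(V[, nd$sources, drop = FALSE] %*% w[nd$slots])
    }
    pre <- pmin(pmax(pre, -PREACT_CLAMP), PREACT_CLAMP)
    V[, nd$col] <- if (nd$is_output) 1 / (1 + exp(-pre)) else apply_activation_id(nd$act, pre)
  }
  V[, plan$output_col]
}

#' Evaluate a genome on feature rows
#'
#' Nodes are evaluated in topological order; each node's pre-activation is
#' the weighted sum of its enabled incoming values (clamped to
#' `[-1e4, 1e4]` to keep unbounded activations finite), the bias node emits
#' constant 1, nodes with no enabled inputs emit `activation(0)`, and the
#' output node applies the sigmoid, so the result is a probability.
#'
#' @param genome A `wann_genome`.
#' @param features Numeric vector of length `n_inputs`, or a matrix/data
#'   frame with `n_inputs` columns (one row per sample).
#' @param weights Either a single scalar shared weight (substituted into
#'   every enabled connection) or a numeric vector with one entry per
#'   enabled connection, indexed by `weight_slot`.
#' @return Numeric vector of probabilities in (0, 1), one per row.
#' @examples
#' g <- minimal_genome(2)
#' forward_pass(g, c(0, 0), weights = 1)  # disconnected output: 0.5
#' @export
forward_pass <- function(genome, features, weights) {
  X <- as_feature_matrix(features, genome$n_inputs)
  forward_compiled(compile_genome(genome), X, weights)
}

as_feature_matrix <- function(features, n_inputs) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (is.null(dim(features))) {
    if (length(features) != n_inputs) {
      stop(sprintf("expected %d features, got %d", n_inputs, length(features)),
           call. = FALSE)
    }
    features <- matrix(features, nrow = 1)
  }
  if (ncol(features) != n_inputs) {
    stop(sprintf("expected %d feature columns, got %d", n_inputs, ncol(features)),
         call. = FALSE)
  }
  storage.mode(features) <- "double"
  if (!all(is.finite(features))) stop("features must be finite", call. = FALSE)
  features
}

#' Read and write genomes as JSON
#'
#' The on-disk form is a human-readable JSON object with keys `nodes`,
#' `connections`, `n_inputs`, `n_outputs` and (when the genome has been
#' weight-trained) `weights`; activations are stored by name. Numbers are
#' written at full precision so a round trip is bit-exact.
#'
#' @param genome A `wann_genome`.
#' @param path File path.
#' @return `read_genome` returns the genome; `write_genome` returns `path`
#'   invisibly.
#' @export
write_genome <- function(genome, path) {
  obj <- list(
    n_inputs = genome$n_inputs,
    n_outputs = genome$n_outputs,
    nodes = genome$nodes,
    connections = genome$connections
  )
  if (!is.null(genome$weights)) obj$weights <- genome$weights
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conns <- obj$connections
  if (is.null(conns) || length(conns) == 0L || nrow(as.data.frame(conns)) == 0L) {
    conns <- empty_connections()
  } else {
    conns <- as.data.frame(conns)
    conns$conn_id <- as.integer(conns$conn_id)
    conns$source <- as.integer(conns$source)
    conns$target <- as.integer(conns$target)
    conns$enabled <- as.logical(conns$enabled)
    conns$weight_slot <- as.integer(conns$weight_slot)
  }
  nodes <- as.data.frame(obj$nodes)
  nodes$node_id <- as.integer(nodes$node_id)
  g <- structure(
    list(nodes = nodes, connections = conns,
         n_inputs = as.integer(obj$n_inputs), n_outputs = as.integer(obj$n_outputs)),
    class = "wann_genome"
  )
  if (!is.null(obj$weights)) g$weights <- as.numeric(obj$weights)
  validate_genome(g)
  g
}
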