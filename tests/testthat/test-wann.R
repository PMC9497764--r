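test_that("initial populations are sparse at the configured rate", {
  cfg0 <- wann_config(population_size = 20, initial_active_fraction = 0)
  expect_true(all(vapply(init_population(cfg0, 10), count_connections,
                         integer(1)) == 0L))
  cfg1 <- wann_config(population_size = 20, initial_active_fraction = 1)
  expect_true(all(vapply(init_population(cfg1, 10), count_connections,
                         integer(1)) == 11L))  # (10 inputs + bias) x 1 output
  set.seed(123)
  cfg <- wann_config(population_size = 200, initial_active_fraction = 0.2)
  pop <- init_population(cfg, 44)
  frac <- mean(vapply(pop, count_connections, integer(1))) / 45
  expect_lt(abs(frac - 0.2), 0.02)
})

test_that("config invariants are enforced", {
  expect_error(wann_config(p_change_activation = 0.6), "sum to 1")
  expect_error(wann_config(shared_weights = c(-1, 0, 1)), "exclude 0")
})

test_that("add-node grows the genome as specified", {
  g <- make_genome(1, character(), data.frame(source = 1, target = 3))
  set.seed(2)
  cfg <- wann_config()
  m <- NULL
  repeat {  # sample mutations until add-node fires on this genome
    m <- mutate_genome(g, cfg)
    if (attr(m, "mutation") == "add_node") break
  }
  expect_identical(nrow(m$nodes), 4L)
  expect_identical(count_connections(m), 2L)
  expect_identical(count_connections(g), 1L)  # input untouched
})

test_that("inapplicable operators fall back in the fixed order", {
  # no hidden nodes and fully saturated pairs: only identity remains
  g <- make_genome(1, character(),
                   data.frame(source = c(1, 2), target = c(3, 3)))
  set.seed(3)
  seen <- character()
  for (i in 1:40) {
    m <- mutate_genome(g, wann_config())
    seen <- c(seen, attr(m, "mutation"))
  }
  # change-activation impossible (no hidden); add-connection impossible
  # (both pairs taken); add-node always possible
  expect_true(all(seen %in% c("add_node")))

  g0 <- minimal_genome(1)  # nothing at all is possible except add-connection
  m0 <- mutate_genome(g0, wann_config())
  expect_true(attr(m0, "mutation") %in% c("add_connection"))
})

test_that("operator frequencies match the configured probabilities", {
  # genome where all three operators are applicable
  g <- make_genome(6, c("relu", "tanh"),
                   data.frame(source = c(1, 2, 3), target = c(9, 10, 8)))
  set.seed(11)
  cfg <- wann_config()
  n <- 10000
  ops <- character(n)
  for (i in seq_len(n)) ops[i] <- attr(mutate_genome(g, cfg), "mutation")
  freq <- table(factor(ops, levels = c("change_activation", "add_node",
                                       "add_connection"))) / n
  expect_lt(abs(freq[["change_activation"]] - 0.50), 0.02)
  expect_lt(abs(freq[["add_node"]] - 0.25), 0.02)
  expect_lt(abs(freq[["add_connection"]] - 0.25), 0.02)
})

test_that("mutation chains never create cycles or lose connections", {
  cfg <- wann_config()
  set.seed(21)
  for (chain in 1:50) {
    g <- init_population(wann_config(population_size = 1,
                                     initial_active_fraction = 0.3), 6)[[1]]
    for (step in 1:10) {
      m <- mutate_genome(g, cfg)
      expect_gte(count_connections(m), count_connections(g))
      expect_true(validate_genome(m))  # includes the acyclicity check
      g <- m
    }
  }
})

test_that("G-mean matches the confusion-matrix formula", {
  expect_equal(gmean_score(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(gmean_score(c(0, 1, 0, 1), c(1, 1, 1, 1)), 0)
  # TP=3 FN=1 TN=2 FP=2 -> sqrt(0.75 * 0.5)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  preds  <- c(1, 1, 1, 0, 1, 1, 0, 0)
  expect_equal(gmean_score(labels, preds), sqrt(0.75 * 0.5),
               tolerance = 1e-12)
  expect_error(gmean_score(c(1, 1), c(1, 0)), "single class")
})

test_that("genome evaluation aggregates per-shared-weight G-means", {
  sw <- c(-2, -1, 1, 2)
  # zero-connection genome: constant 0.5 output, all predicted positive
  rec0 <- evaluate_genome(minimal_genome(2),
                          matrix(stats::rnorm(20), 10), rep(0:1, 5), sw)
  expect_equal(rec0$mean_perf, 0)
  expect_equal(rec0$best_perf, 0)
  expect_identical(rec0$n_connections, 0L)

  # 1-connection genome on a 4-row hand dataset, verified weight by weight
  g <- make_genome(1, character(), data.frame(source = 1, target = 3))
  X <- matrix(c(-1, -0.2, 0.4, 2), 4)
  y <- c(0, 0, 1, 1)
  manual <- vapply(sw, function(w) {
    p <- 1 / (1 + exp(-w * X[, 1]))
    gmean_score(y, as.numeric(p >= 0.5))
  }, numeric(1))
  rec <- evaluate_genome(g, X, y, sw)
  expect_equal(rec$mean_perf, mean(manual), tolerance = 1e-12)
  expect_equal(rec$best_perf, max(manual), tolerance = 1e-12)
  expect_gte(rec$best_perf, rec$mean_perf)
})

test_that("nsga2 fronts match hand dominance and the brute-force oracle", {
  r1 <- data.frame(mean_perf = c(0.9, 0.8), best_perf = c(0.95, 0.85),
                   n_connections = c(10, 20))
  expect_identical(nsga2_rank(r1)$front, c(0L, 1L))
  r2 <- data.frame(mean_perf = c(0.9, 0.8), best_perf = c(0.95, 0.85),
                   n_connections = c(20, 10))
  expect_identical(nsga2_rank(r2)$front, c(0L, 0L))

  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:50, 1)
    recs <- data.frame(mean_perf = round(stats::runif(n), 2),
                       best_perf = round(stats::runif(n), 2),
                       n_connections = sample(0:30, n, replace = TRUE))
    expect_identical(nsga2_rank(recs)$front, bf_pareto_fronts(recs),
                     info = paste("instance", s))
  }
})

test_that("crowding distance puts boundary points at infinity", {
  recs <- data.frame(mean_perf = c(0.1, 0.5, 0.9),
                     best_perf = c(0.1, 0.5, 0.9),
                     n_connections = c(10, 20, 30))
  rk <- nsga2_rank(recs)
  expect_identical(rk$front, c(0L, 0L, 0L))
  expect_identical(is.infinite(rk$crowding), c(TRUE, FALSE, TRUE))
})

test_that("tournament selection prefers lower fronts, then crowding", {
  pop <- init_population(wann_config(population_size = 4,
                                     initial_active_fraction = 0.5), 3)
  ranks <- tibble::tibble(front = c(2L, 0L, 2L, 2L),
                          crowding = c(1, 0.5, 2, 3))
  set.seed(1)
  for (i in 1:20) {
    # a size-50 tournament on 4 members includes the front-0 member
    # with overwhelming probability, and it must then win
    w <- tournament_select(pop, ranks, size = 50)
    expect_identical(attr(w, "pop_index"), 2L)
  }
  # single-member population returns that member
  w1 <- tournament_select(pop[1], tibble::tibble(front = 0L, crowding = Inf), 4)
  expect_identical(attr(w1, "pop_index"), 1L)
})

test_that("tournament frequencies match exhaustive enumeration", {
  ranks <- tibble::tibble(front = c(0L, 0L, 1L, 1L, 2L),
                          crowding = c(Inf, 1, Inf, 2, Inf))
  n <- nrow(ranks)
  # enumerate all 5^4 ordered draws and apply the deterministic win rule
  draws <- expand.grid(rep(list(seq_len(n)), 4))
  win_of <- function(cand) {
    best <- cand[1]
    for (i in cand[-1]) {
      if (ranks$front[i] < ranks$front[best] ||
          (ranks$front[i] == ranks$front[best] &&
           ranks$crowding[i] > ranks$crowding[best]) ||
          (ranks$front[i] == ranks$front[best] &&
           ranks$crowding[i] == ranks$crowding[best] && i < best)) best <- i
    }
    best
  }
  exact <- table(factor(apply(draws, 1, win_of), levels = seq_len(n))) /
    nrow(draws)
  set.seed(99)
  sim <- table(factor(replicate(10000,
    wannmwr:::tournament_select_index(ranks, 4)), levels = seq_len(n))) / 10000
  expect_true(all(abs(exact - sim) < 0.02))
})

test_that("the search loop runs, improves over chance, and is reproducible", {
  train <- make_separable_task(80, 1)
  val <- make_separable_task(40, 2)
  cfg <- wann_config(generations = 10, population_size = 32, seed = 5)
  res <- run_wann_search(train, val, cfg)
  expect_identical(nrow(res$history), 10L)
  expect_gt(res$best_val_perf, 0.5)  # better than chance-level G-mean
  expect_s3_class(res$best_genome, "wann_genome")

  res2 <- run_wann_search(train, val, cfg)
  expect_identical(res2$history, res$history)
  expect_identical(res2$best_genome$connections, res$best_genome$connections)

  res0 <- run_wann_search(train, val,
                          wann_config(generations = 0, population_size = 16,
                                      seed = 5))
  expect_identical(nrow(res0$history), 0L)
  expect_s3_class(res0$best_genome, "wann_genome")  # best of the initial pop
})

test_that("best single-weight score never falls below the mean score", {
  split <- make_small_split(31, n = 30)
  pop <- init_population(wann_config(population_size = 20,
                                     initial_active_fraction = 0.3), 44)
  f <- setdiff(names(split$train), "risk")
  for (g in pop) {
    rec <- evaluate_genome(g, split$train[f], split$train$risk)
    expect_gte(rec$best_perf, rec$mean_perf)
  }
})
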