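test_that("cross-entropy matches hand arithmetic and clips safely", {
  expect_equal(cross_entropy(1, 1 - 1e-12), 0, tolerance = 1e-9)
  expect_equal(cross_entropy(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(c(1, 0), c(0.9, 0.2)),
               (-log(0.9) - log(0.8)) / 2, tolerance = 1e-12)
  expect_true(is.finite(cross_entropy(c(1, 0), c(0, 1))))  # clipped at eps
  expect_error(cross_entropy(c(1, 0), 0.5), "equal length")
})

test_that("the shared-weight scan is the grid argmin with |w| tie-breaks", {
  # zero-connection genome: constant loss, returns the point nearest 0
  g0 <- minimal_genome(2)
  w0 <- scan_shared_weight(g0, matrix(stats::rnorm(10), 5), c(0, 1, 0, 1, 0))
  expect_equal(as.numeric(w0), 0)

  # 1-connection toy genome: the grid is its own brute-force oracle
  g <- make_genome(1, character(), data.frame(source = 1, target = 3))
  X <- matrix(c(-2, -1, 1, 2), 4)
  y <- c(0, 0, 1, 1)
  w <- scan_shared_weight(g, X, y, n_points = 21)
  grid <- seq(-2, 2, length.out = 21)
  losses <- vapply(grid, function(wi)
    cross_entropy(y, 1 / (1 + exp(-wi * X[, 1]))), numeric(1))
  expect_equal(as.numeric(w), grid[which.min(losses)])
  sc <- attr(w, "scan")
  expect_equal(sc$loss, losses, tolerance = 1e-12)

  # symmetric loss: a 0/1 label swap mirrors the loss, tie-break picks |w|
  ysym <- c(1, 0, 0, 1)
  wsym <- scan_shared_weight(g, X, ysym, n_points = 5)
  expect_equal(abs(as.numeric(wsym)),
               min(abs(seq(-2, 2, length.out = 5)[
                 which(abs(attr(wsym, "scan")$loss -
                             min(attr(wsym, "scan")$loss)) < 1e-12)])))
})

test_that("cmaes solves smooth benchmarks to tight tolerances", {
  set.seed(1)
  res1 <- cmaes_minimize(function(x) (x - 3)^2, 0, sigma0 = 1, budget = 2000)
  expect_lt(abs(res1$best_par - 3), 1e-5)

  sphere <- function(x) sum(x^2)
  res5 <- cmaes_minimize(sphere, rep(3, 5), sigma0 = 1, budget = 5000)
  expect_lt(res5$best_value, 1e-10)
  expect_lte(res5$evaluations, 5000)
})

test_that("cmaes trajectories are seed-reproducible and monotone in best", {
  f <- function(x) sum((x - 1)^2) + 0.1 * sum(sin(5 * x)^2)
  set.seed(42)
  a <- cmaes_minimize(f, rep(0, 4), 0.5, budget = 800)
  set.seed(42)
  b <- cmaes_minimize(f, rep(0, 4), 0.5, budget = 800)
  expect_identical(a$best_par, b$best_par)
  expect_identical(a$history, b$history)
  expect_true(all(diff(a$history$best_value) <= 0))
})

test_that("cmaes propagates non-finite objective values with context", {
  set.seed(1)
  expect_error(cmaes_minimize(function(x) NaN, c(0, 0), 1, budget = 100),
               "non-finite")
})

test_that("bipop doubles the population across restarts", {
  # a flat objective stagnates every run, exposing the restart schedule
  flat <- function(x) 1
  cfg <- bipop_config(max_evaluations = 6000, max_restarts = 3,
                      patience = 5, seed = 7)
  res <- bipop_optimize(flat, rep(3, 5), cfg)
  expect_gte(nrow(res$restarts), 3)
  expect_identical(res$restarts$lambda[1:3], c(50, 100, 200))
  expect_true(all(res$restarts$stop_reason[1:3] == "stagnation"))

  rastrigin <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))
  cfg2 <- bipop_config(max_evaluations = 4000, max_restarts = 2,
                       patience = 5, seed = 7)
  res2 <- bipop_optimize(rastrigin, rep(3, 5), cfg2)
  expect_equal(res2$best_value, min(res2$restarts$best_value))
  # restarting can only improve on the first run alone
  expect_lte(res2$best_value, res2$restarts$best_value[1])
})

test_that("bipop with no restarts equals one cmaes run", {
  f <- function(x) sum(x^2)
  cfg <- bipop_config(max_restarts = 0, max_evaluations = 1000,
                      patience = 50, sigma0 = 0.5, seed = 3)
  res <- bipop_optimize(f, rep(2, 3), cfg)
  set.seed(3)
  single <- cmaes_minimize(f, rep(2, 3), 0.5, lambda = 50, budget = 1000,
                           patience = 50, keep_history = FALSE)
  expect_identical(res$best_value, single$best_value)
  expect_identical(res$best_par, single$best_par)
})

test_that("weight training starts from the scan and selects by validation", {
  split <- make_small_split(17, n = 40)
  g <- make_genome(44, "absolute",
                   data.frame(source = c(2, 4, 6, 8, 45, 47),
                              target = c(46, 46, 47, 47, 46, 46)))
  expect_error(train_wann_weights(minimal_genome(44), split$train,
                                  split$validation),
               "nothing to train")

  fit <- train_wann_weights(g, split$train, split$validation,
                            bipop_config(max_evaluations = 300, seed = 2))
  expect_identical(nrow(fit$history), fit$evaluations)
  # running-minimum model selection: never worse than the scanned start
  expect_lte(fit$best_val_loss, fit$history$val_loss[1])
  expect_length(fit$weights, count_connections(g))
  expect_identical(fit$genome$weights, fit$weights)
})

test_that("training improves a separable task beyond the shared weight", {
  train <- make_separable_task(100, 3)
  val <- make_separable_task(60, 4)
  test <- make_separable_task(60, 5)
  g <- make_genome(2, character(),
                   data.frame(source = c(1, 2, 3), target = c(4, 4, 4)))
  fit <- train_wann_weights(g, train, val,
                            bipop_config(max_evaluations = 600, seed = 6))
  f <- c("x1", "x2")
  w0 <- scan_shared_weight(g, as.matrix(train[f]), train$risk)
  p_shared <- forward_pass(g, as.matrix(test[f]), as.numeric(w0))
  p_fit <- forward_pass(g, as.matrix(test[f]), fit$weights)
  g_shared <- gmean_score(test$risk, as.numeric(p_shared >= 0.5))
  g_fit <- gmean_score(test$risk, as.numeric(p_fit >= 0.5))
  expect_gte(g_fit, g_shared)
})
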