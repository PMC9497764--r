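#' Evaluate a topology under the four weight schemes
#'
#' The robustness ablation for a weight-agnostic topology: test-set
#' performance when every connection carries (a) a random shared weight
#' (averaged over `n_random` uniform draws from `[-2, 2]`), (b) the fixed
#' shared evaluation weights (averaged over the set), (c) the linearly
#' scanned tuned shared weight, and (d) the trained per-connection weight
#' vector, when one is supplied.
#'
#' @param genome A `wann_genome`.
#' @param train Data frame used to tune the shared weight.
#' @param test Data frame scored by every scheme.
#' @param trained_weights Optional weight vector from
#'   [train_wann_weights()].
#' @param shared_weights Fixed shared weights (defaults to the search set).
#' @param n_random Random shared-weight draws to average.
#' @param seed Optional integer seed for the random draws.
#' @param label_col Label column name.
#' @return Tibble with one row per scheme: `scheme`, `gmean`, `f1`,
#'   `accuracy`, `precision`, `recall`.
#' @export
evaluate_weight_schemes <- function(genome, train, test,
                                    trained_weights = NULL,
                                    shared_weights = wann_config()$shared_weights,
                                    n_random = 10L, seed = NULL,
                                    label_col = "risk") {
  if (!is.null(seed)) set.seed(seed)
  tr <- split_xy(train, label_col)
  te <- split_xy(test, label_col)
  plan <- compile_genome(genome)
  score <- function(w) {
    p <- forward_compiled(plan, te$X, w)
    r <- classification_report(te$y, p, genome = genome)
    c(gmean = r$gmean, f1 = r$f1, accuracy = r$accuracy,
      precision = r$precision, recall = r$recall)
  }
  avg <- function(ws) rowMeans(vapply(ws, score, numeric(5)))
  rows <- list(
    random = avg(stats::runif(n_random, -2, 2)),
    fixed_shared = avg(shared_weights),
    tuned_shared = score(as.numeric(scan_shared_weight(genome, tr$X, tr$y)))
  )
  if (!is.null(trained_weights)) rows$trained <- score(trained_weights)
  dplyr::bind_cols(
    tibble::tibble(scheme = names(rows)),
    tibble::as_tibble(do.call(rbind, rows))
  )
}

#' Run the full two-phase experiment
#'
#' For each seed: balance and split the data (60/20/20, stratified), run
#' the weight-agnostic topology search on train/validation, tune the best
#' genome's weights with BIPOP-CMA-ES, and score both the untrained
#' (tuned-shared-weight) and trained models on the held-out test set;
#' optionally also grow the cascade-correlation baseline. Models are then
#' compared pairwise on per-sample absolute test errors.
#'
#' @param data Tibble in the MWR schema; by default a synthetic dataset is
#'   generated per seed from `synthetic`.
#' @param synthetic A [synthetic_config()] used when `data` is `NULL`.
#' @param seeds Integer seeds, one full pipeline run each.
#' @param wann,bipop,ccnn Phase configurations.
#' @param balance Balance classes before splitting.
#' @param standardize Standardize features with training-set statistics
#'   (see [standardize_split()]).
#' @param run_ccnn Also train the cascade-correlation baseline.
#' @param label_col Label column name.
#' @return An `mwr_experiment`: `metrics` (tibble: seed, model, f1,
#'   accuracy, precision, recall, gmean, connections), `summary`
#'   (mean +/- sd per model over seeds), `comparisons` (paired t-test and
#'   mean output difference, trained vs. each other model, per seed), and
#'   `runs` (per-seed artifacts: search, fit, reports).
#' @export
run_mwr_experiment <- function(data = NULL, synthetic = synthetic_config(),
                               seeds = c(1L, 2L, 3L),
                               wann = wann_config(), bipop = bipop_config(),
                               ccnn = ccnn_config(), balance = TRUE,
                               standardize = TRUE,
                               run_ccnn = FALSE, label_col = "risk") {
  stopifnot(length(seeds) >= 1)
  metrics <- list(); comparisons <- list(); runs <- list()
  for (seed in seeds) {
    dat <- if (is.null(data)) {
      cfg <- synthetic; cfg$seed <- seed
      generate_synthetic_mwr(cfg)
    } else data
    parts <- prepare_mwr(dat, seed = seed, balance = balance,
                         standardize = standardize)

    wann_cfg <- wann; wann_cfg$seed <- seed
    search <- run_wann_search(parts$train, parts$validation, wann_cfg,
                              label_col = label_col)
    genome <- search$best_genome

    bipop_cfg <- bipop; bipop_cfg$seed <- seed
    fit <- train_wann_weights(genome, parts$train, parts$validation,
                              bipop_cfg, label_col = label_col)

    te <- split_xy(parts$test, label_col)
    tr <- split_xy(parts$train, label_col)
    plan <- compile_genome(genome)
    w_tuned <- as.numeric(scan_shared_weight(genome, tr$X, tr$y))
    p_untrained <- forward_compiled(plan, te$X, w_tuned)
    p_trained <- forward_compiled(plan, te$X, fit$weights)
    rep_untrained <- classification_report(te$y, p_untrained, genome = genome)
    rep_trained <- classification_report(te$y, p_trained, genome = genome)

    row <- function(model, r) tibble::tibble(
      seed = seed, model = model, f1 = r$f1, accuracy = r$accuracy,
      precision = r$precision, recall = r$recall, gmean = r$gmean,
      connections = r$n_connections)
    metrics[[length(metrics) + 1]] <- row("wann", rep_untrained)
    metrics[[length(metrics) + 1]] <- row("wann_bipop_cmaes", rep_trained)

    cmp <- paired_comparison_test(abs(p_trained - te$y), abs(p_untrained - te$y))
    mod <- mean_output_difference(p_trained, p_untrained)
    comparisons[[length(comparisons) + 1]] <- tibble::tibble(
      seed = seed, model_a = "wann_bipop_cmaes", model_b = "wann",
      t_statistic = cmp$statistic, p_value = cmp$p_value,
      mean_diff = mod$mean, sd_diff = mod$sd)

    ccnn_fit_obj <- NULL
    if (run_ccnn) {
      ccnn_cfg <- ccnn; ccnn_cfg$seed <- seed
      ccnn_fit_obj <- train_ccnn(parts$train, parts$validation, ccnn_cfg,
                                 label_col = label_col)
      p_ccnn <- predict(ccnn_fit_obj, te$X)
      rep_ccnn <- classification_report(
        te$y, p_ccnn,
        n_connections = ccnn_connection_count(ncol(te$X),
                                              length(ccnn_fit_obj$network$hidden)))
      metrics[[length(metrics) + 1]] <- row("ccnn", rep_ccnn)
      cmp2 <- paired_comparison_test(abs(p_trained - te$y), abs(p_ccnn - te$y))
      mod2 <- mean_output_difference(p_trained, p_ccnn)
      comparisons[[length(comparisons) + 1]] <- tibble::tibble(
        seed = seed, model_a = "wann_bipop_cmaes", model_b = "ccnn",
        t_statistic = cmp2$statistic, p_value = cmp2$p_value,
        mean_diff = mod2$mean, sd_diff = mod2$sd)
    }

    runs[[as.character(seed)]] <- list(
      split = parts, search = search, fit = fit, ccnn = ccnn_fit_obj,
      reports = list(wann = rep_untrained, wann_bipop_cmaes = rep_trained))
  }
  metrics <- dplyr::bind_rows(metrics)
  summary <- if (length(seeds) >= 2) {
    dplyr::group_by(metrics, .data$model) |>
      dplyr::summarise(dplyr::across(
        c("f1", "accuracy", "precision", "recall", "gmean", "connections"),
        list(mean = mean, sd = stats::sd)), .groups = "drop")
  } else NULL
  structure(list(metrics = metrics, summary = summary,
                 comparisons = dplyr::bind_rows(comparisons), runs = runs),
            class = "mwr_experiment")
}

#' @export
print.mwr_experiment <- function(x, ...) {
  cat("<mwr_experiment>\n")
  print(x$metrics)
  invisible(x)
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys `seeds`, `wann`, `bipop`, `ccnn`, `synthetic`, `data`
#' (path), `balance`, `run_ccnn`; each sub-map holds the corresponding
#' configuration constructor's arguments. Missing keys fall back to the
#' defaults.
#'
#' @param path YAML file path.
#' @return Named list of resolved configurations ready for
#'   [run_mwr_experiment()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, as.list(args %||% list()))
  list(
    seeds = as.integer(y$seeds %||% c(1L, 2L, 3L)),
    data = y$data,
    balance = isTRUE(y$balance %||% TRUE),
    run_ccnn = isTRUE(y$run_ccnn %||% FALSE),
    wann = build(wann_config, y$wann),
    bipop = build(bipop_config, y$bipop),
    ccnn = build(ccnn_config, y$ccnn),
    synthetic = build(synthetic_config, y$synthetic)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
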