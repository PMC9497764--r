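#' The 44-point MWR measurement schema
#'
#' Per mammary gland, ten positions are measured — the nipple (0), eight
#' points around it (1-8) and the axillary point (9) — each both on the skin
#' and at 3-5 cm depth, giving 40 columns; two reference points below the
#' chest (t1, t2), again skin and depth, complete the 44. Columns are named
#' `<side><position>_<layer>` (e.g. `l0_depth`, `r9_skin`) and `t1_skin`,
#' `t1_depth`, `t2_skin`, `t2_depth`.
#'
#' @return Character vector of the 44 feature column names, in canonical
#'   order.
#' @export
mwr_feature_names <- function() {
  gland <- as.vector(t(outer(c("l", "r"), 0:9, paste0)))
  c(paste0(rep(gland, each = 2), c("_skin", "_depth")),
    paste0(rep(c("t1", "t2"), each = 2), c("_skin", "_depth")))
}

#' Load an MWR temperature table
#'
#' Reads a delimited text file with a header row, maps its columns onto the
#' canonical 44-feature schema (by default the canonical names themselves;
#' pass `column_map` to rename) and the label column onto 0/1, and drops
#' rows with missing or unparseable values, reporting the count via a
#' message.
#'
#' @param path Path to a delimited text file.
#' @param label_col Name of the label column in the file.
#' @param column_map Optional named character vector mapping file column
#'   names to canonical names (`c(file_name = "l0_skin", ...)`).
#' @param sep Field separator.
#' @return Tibble with the 44 feature columns (numeric, degrees Celsius)
#'   and `risk` (integer 0 = low, 1 = high), with attribute
#'   `provenance = "real"` and `n_dropped`.
#' @export
load_mwr_table <- function(path, label_col = "risk", column_map = NULL,
                           sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
  if (!is.null(column_map)) {
    hits <- match(names(column_map), names(raw))
    if (anyNA(hits)) {
      stop("column_map names not in file: ",
           paste(names(column_map)[is.na(hits)], collapse = ", "))
    }
    names(raw)[hits] <- unname(column_map)
  }
  want <- mwr_feature_names()
  missing_cols <- setdiff(c(want, label_col), names(raw))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  feats <- raw[want]
  for (j in seq_along(feats)) {
    feats[[j]] <- suppressWarnings(as.numeric(feats[[j]]))
  }
  lab <- raw[[label_col]]
  if (is.character(lab)) {
    lab <- dplyr::case_match(tolower(trimws(lab)),
                             c("0", "low", "low-risk", "healthy") ~ 0L,
                             c("1", "high", "high-risk", "sick") ~ 1L,
                             .default = NA_integer_)
  } else {
    lab <- ifelse(lab %in% c(0, 1), as.integer(lab), NA_integer_)
  }
  ok <- stats::complete.cases(feats) & !is.na(lab)
  n_dropped <- sum(!ok)
  if (n_dropped) {
    message(sprintf("load_mwr_table: dropped %d row(s) with missing or unparseable values", n_dropped))
  }
  out <- tibble::as_tibble(feats[ok, , drop = FALSE])
  out$risk <- lab[ok]
  attr(out, "provenance") <- "real"
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write an MWR table
#'
#' Writes the dataset as comma-separated text with a header, the schema
#' [load_mwr_table()] reads back.
#'
#' @param data Tibble with the 44 feature columns and `risk`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mwr_table <- function(data, path) {
  utils::write.csv(as.data.frame(data)[c(mwr_feature_names(), "risk")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Balance classes by undersampling the majority
#'
#' Randomly undersamples the majority class without replacement down to the
#' minority count, then shuffles the row order. Undersampling keeps only
#' real measurements (no synthetic interpolation).
#'
#' @param data Tibble with a `risk` column containing both classes.
#' @param seed Optional integer seed.
#' @return Balanced, shuffled tibble.
#' @export
balance_classes <- function(data, seed = NULL) {
  y <- data$risk  # force `data` before seeding so call nesting cannot
                  # reorder the RNG stream
  if (!is.null(seed)) set.seed(seed)
  if (length(unique(y)) < 2) stop("both classes must be present")
  counts <- table(y)
  n_min <- min(counts)
  keep <- unlist(lapply(names(counts), function(cl) {
    idx <- which(y == as.numeric(cl))
    if (length(idx) > n_min) sample(idx, n_min) else idx
  }))
  data[sample(keep), , drop = FALSE]
}

#' Stratified train/validation/test split
#'
#' Splits by label so each subset's class sizes are within one row of the
#' exact fractions per class; subsets are disjoint and exhaustive. The test
#' partition is intended to stay untouched until final evaluation.
#'
#' @param data Tibble with a `risk` column (each class needs >= 3 rows).
#' @param fractions Length-3 proportions summing to 1 (train, validation,
#'   test).
#' @param seed Optional integer seed.
#' @return Named list of tibbles: `train`, `validation`, `test`, of class
#'   `mwr_split`.
#' @export
split_mwr <- function(data, fractions = c(0.6, 0.2, 0.2), seed = NULL) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0))
  y <- data$risk  # force before seeding (see balance_classes)
  if (!is.null(seed)) set.seed(seed)
  counts <- table(y)
  if (any(counts < 3) && all(fractions > 0)) {
    stop("each class needs at least 3 rows for a stratified 3-way split")
  }
  idx <- list(train = integer(), validation = integer(), test = integer())
  for (cl in names(counts)) {
    rows <- sample(which(y == as.numeric(cl)))
    n <- length(rows)
    n_tr <- round(fractions[1] * n)
    n_va <- round(fractions[2] * n)
    n_va <- min(n_va, n - n_tr)
    n_te <- n - n_tr - n_va
    idx$train <- c(idx$train, rows[seq_len(n_tr)])
    idx$validation <- c(idx$validation, rows[n_tr + seq_len(n_va)])
    idx$test <- c(idx$test, rows[n_tr + n_va + seq_len(n_te)])
  }
  structure(lapply(idx, function(i) data[sort(i), , drop = FALSE]),
            class = "mwr_split")
}

#' Configuration for the synthetic MWR generator
#'
#' The generator emulates the structure of bilateral MWR thermometry: skin
#' temperatures around 33.5 degC, depth temperatures around 36.5 degC,
#' Gaussian measurement noise shared between the two glands at each
#' position, a small independent left/right asymmetry for low-risk rows,
#' and, for high-risk rows, a contiguous unilateral depth hotspot (with half
#' the excess on the overlying skin points) breaking the symmetry.
#'
#' @param n_low,n_high Rows per class.
#' @param skin_baseline,depth_baseline Mean temperatures (degC).
#' @param noise_sd Measurement noise sd (degC), shared across sides.
#' @param hotspot_delta Depth-temperature excess of a hotspot (degC).
#' @param hotspot_points Number of contiguous positions in a hotspot.
#' @param asymmetry_sd Sd of the left-minus-right difference for healthy
#'   tissue (degC).
#' @param seed Optional integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_low = 200L, n_high = 200L,
                             skin_baseline = 33.5, depth_baseline = 36.5,
                             noise_sd = 0.4, hotspot_delta = 1.5,
                             hotspot_points = 3L, asymmetry_sd = 0.15,
                             seed = NULL) {
  stopifnot(n_low + n_high >= 10, noise_sd >= 0, asymmetry_sd >= 0,
            hotspot_points >= 1, hotspot_points <= 10)
  structure(list(
    n_low = as.integer(n_low), n_high = as.integer(n_high),
    skin_baseline = skin_baseline, depth_baseline = depth_baseline,
    noise_sd = noise_sd, hotspot_delta = hotspot_delta,
    hotspot_points = as.integer(hotspot_points),
    asymmetry_sd = asymmetry_sd, seed = seed
  ), class = "synthetic_config")
}

#' Generate a synthetic MWR-like dataset
#'
#' Low-risk rows are baseline temperatures plus position-wise Gaussian noise
#' shared by the left and right gland, plus an independent per-side
#' perturbation scaled so the left-minus-right difference has standard
#' deviation `asymmetry_sd`. High-risk rows additionally receive
#' `hotspot_delta` degC on `hotspot_points` contiguous depth positions
#' (wrapping over the 10 gland positions) of one randomly chosen gland, and
#' half that excess on the corresponding skin positions. Rows are shuffled.
#'
#' @param config A [synthetic_config()].
#' @return Tibble in the [mwr_feature_names()] schema plus `risk`, with
#'   attribute `provenance = "synthetic"`.
#' @export
generate_synthetic_mwr <- function(config = synthetic_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_low + config$n_high
  labels <- rep(c(0L, 1L), c(config$n_low, config$n_high))
  side_sd <- config$asymmetry_sd / sqrt(2)

  # vectorized construction, column-major over the schema
  feats <- matrix(0, nrow = n, ncol = 44,
                  dimnames = list(NULL, mwr_feature_names()))
  skin_common <- matrix(stats::rnorm(n * 10, 0, config$noise_sd), n, 10)
  depth_common <- matrix(stats::rnorm(n * 10, 0, config$noise_sd), n, 10)
  skin_l <- config$skin_baseline + skin_common + matrix(stats::rnorm(n * 10, 0, side_sd), n, 10)
  skin_r <- config$skin_baseline + skin_common + matrix(stats::rnorm(n * 10, 0, side_sd), n, 10)
  depth_l <- config$depth_baseline + depth_common + matrix(stats::rnorm(n * 10, 0, side_sd), n, 10)
  depth_r <- config$depth_baseline + depth_common + matrix(stats::rnorm(n * 10, 0, side_sd), n, 10)

  high_rows <- which(labels == 1L)
  if (length(high_rows)) {
    sides <- sample(c("l", "r"), length(high_rows), replace = TRUE)
    starts <- sample.int(10, length(high_rows), replace = TRUE)
    for (i in seq_along(high_rows)) {
      r <- high_rows[i]
      pts <- ((starts[i] - 1 + seq_len(config$hotspot_points) - 1) %% 10) + 1
      if (sides[i] == "l") {
        depth_l[r, pts] <- depth_l[r, pts] + config$hotspot_delta
        skin_l[r, pts] <- skin_l[r, pts] + config$hotspot_delta / 2
      } else {
        depth_r[r, pts] <- depth_r[r, pts] + config$hotspot_delta
        skin_r[r, pts] <- skin_r[r, pts] + config$hotspot_delta / 2
      }
    }
  }
  for (p in 0:9) {
    feats[, sprintf("l%d_skin", p)] <- skin_l[, p + 1]
    feats[, sprintf("l%d_depth", p)] <- depth_l[, p + 1]
    feats[, sprintf("r%d_skin", p)] <- skin_r[, p + 1]
    feats[, sprintf("r%d_depth", p)] <- depth_r[, p + 1]
  }
  feats[, "t1_skin"] <- config$skin_baseline + stats::rnorm(n, 0, config$noise_sd)
  feats[, "t1_depth"] <- config$depth_baseline + stats::rnorm(n, 0, config$noise_sd)
  feats[, "t2_skin"] <- config$skin_baseline + stats::rnorm(n, 0, config$noise_sd)
  feats[, "t2_depth"] <- config$depth_baseline + stats::rnorm(n, 0, config$noise_sd)

  ord <- sample.int(n)
  out <- tibble::as_tibble(as.data.frame(feats[ord, , drop = FALSE]))
  out$risk <- labels[ord]
  attr(out, "provenance") <- "synthetic"
  out
}
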