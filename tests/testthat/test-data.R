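fixture_path <- system.file("extdata", "mwr_synthetic_6rows.csv",
                            package = "wannmwr")

test_that("the schema has 44 canonical columns", {
  nm <- mwr_feature_names()
  expect_length(nm, 44)
  expect_identical(anyDuplicated(nm), 0L)
  expect_identical(sum(grepl("_depth$", nm)), 22L)
  expect_identical(sum(grepl("_skin$", nm)), 22L)
  expect_true(all(c("l0_skin", "r9_depth", "t1_skin", "t2_depth") %in% nm))
})

test_that("the packaged fixture loads as 6 patients x 44 temperatures", {
  d <- load_mwr_table(fixture_path)
  expect_identical(nrow(d), 6L)
  expect_identical(ncol(d), 45L)  # 44 features + risk
  expect_true(all(d$risk %in% 0:1))
  expect_identical(attr(d, "provenance"), "real")
  expect_identical(attr(d, "n_dropped"), 0L)
})

test_that("rows with missing cells are dropped with a reported count", {
  lines <- readLines(fixture_path)
  fields <- strsplit(lines[3], ",")[[1]]
  fields[5] <- ""
  lines[3] <- paste(fields, collapse = ",")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, path)
  expect_message(d <- load_mwr_table(path), "dropped 1 row")
  expect_identical(nrow(d), 5L)
  expect_identical(attr(d, "n_dropped"), 1L)
})

test_that("missing required columns are listed in the error", {
  d <- utils::read.csv(fixture_path, check.names = FALSE)
  d$l0_skin <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(load_mwr_table(path), "l0_skin")
})

test_that("column maps and textual labels are translated", {
  d <- utils::read.csv(fixture_path, check.names = FALSE)
  names(d)[names(d) == "l0_skin"] <- "Skin L0"
  d$risk <- ifelse(d$risk == 1, "High", "low")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, path, row.names = FALSE)
  out <- load_mwr_table(path, column_map = c("Skin L0" = "l0_skin"))
  expect_identical(nrow(out), 6L)
  expect_identical(sum(out$risk), 4L)
})

test_that("balancing undersamples the majority to the minority count", {
  d <- generate_synthetic_mwr(synthetic_config(n_low = 80, n_high = 20,
                                               seed = 3))
  b <- balance_classes(d, seed = 1)
  expect_identical(sum(b$risk == 0), 20L)
  expect_identical(sum(b$risk == 1), 20L)
  # same seed, same selected rows
  b2 <- balance_classes(d, seed = 1)
  expect_identical(b, b2)
  # already balanced: counts preserved
  d2 <- generate_synthetic_mwr(synthetic_config(n_low = 30, n_high = 30,
                                                seed = 4))
  expect_identical(nrow(balance_classes(d2, seed = 1)), 60L)
})

test_that("the stratified split hits the 60/20/20 sizes exactly", {
  d <- generate_synthetic_mwr(synthetic_config(n_low = 535, n_high = 535,
                                               seed = 5))
  parts <- split_mwr(d, seed = 1)
  expect_identical(vapply(parts, nrow, integer(1)),
                   c(train = 642L, validation = 214L, test = 214L))
  # per-class stratification within one row of exact
  for (p in parts) {
    expect_lte(abs(sum(p$risk == 0) - sum(p$risk == 1)), 1)
  }
  # disjoint and exhaustive
  key <- function(p) do.call(paste, c(as.list(p), sep = "|"))
  all_keys <- c(key(parts$train), key(parts$validation), key(parts$test))
  expect_identical(sort(all_keys), sort(key(d)))
})

test_that("degenerate splits behave as specified", {
  d <- generate_synthetic_mwr(synthetic_config(n_low = 20, n_high = 20,
                                               seed = 6))
  all_train <- split_mwr(d, fractions = c(1, 0, 0), seed = 1)
  expect_identical(nrow(all_train$train), 40L)
  expect_identical(nrow(all_train$test), 0L)
  tiny <- d[c(which(d$risk == 0)[1:10], which(d$risk == 1)[1:2]), ]
  expect_error(split_mwr(tiny, seed = 1), "at least 3 rows")
})

test_that("the generator is deterministic and balanced by construction", {
  cfg <- synthetic_config(n_low = 25, n_high = 25, seed = 9)
  d1 <- generate_synthetic_mwr(cfg)
  d2 <- generate_synthetic_mwr(cfg)
  expect_identical(d1, d2)
  expect_identical(sum(d1$risk == 0), 25L)
  expect_identical(sum(d1$risk == 1), 25L)
})

test_that("zero noise and zero hotspot collapse both classes to one row", {
  d <- generate_synthetic_mwr(synthetic_config(
    n_low = 10, n_high = 10, noise_sd = 0, asymmetry_sd = 0,
    hotspot_delta = 0, seed = 1))
  feats <- as.matrix(d[mwr_feature_names()])
  expect_true(all(apply(feats, 2, function(x) diff(range(x))) == 0))
  expect_equal(unname(colMeans(feats[, grepl("_depth$", colnames(feats))])),
               rep(36.5, 22))
})

test_that("strong hotspots are separable by the left-right depth gap", {
  d <- generate_synthetic_mwr(synthetic_config(
    n_low = 60, n_high = 60, hotspot_delta = 5, noise_sd = 0.01, seed = 2))
  m <- as.matrix(d[mwr_feature_names()])
  gap <- apply(abs(m[, sprintf("l%d_depth", 0:9)] -
                     m[, sprintf("r%d_depth", 0:9)]), 1, max)
  thr <- 2.5
  expect_identical(as.integer(gap > thr), d$risk)
})

test_that("low-risk depth means match the configured baseline (CLT bound)", {
  cfg <- synthetic_config(n_low = 400, n_high = 10, noise_sd = 0.4, seed = 7)
  d <- generate_synthetic_mwr(cfg)
  low <- as.matrix(d[d$risk == 0, sprintf("l%d_depth", 0:9)])
  se <- cfg$noise_sd / sqrt(nrow(low))
  expect_true(all(abs(colMeans(low) - cfg$depth_baseline) < 3 * 1.2 * se))
})

test_that("write/load round-trips the schema", {
  d <- generate_synthetic_mwr(synthetic_config(n_low = 8, n_high = 8,
                                               seed = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mwr_table(d, path)
  d2 <- load_mwr_table(path)
  expect_equal(as.data.frame(d2), as.data.frame(d[names(d2)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("standardization uses train statistics only", {
  split <- make_small_split(8, n = 40)
  f <- setdiff(names(split$train), "risk")
  expect_equal(unname(colMeans(as.matrix(split$train[f]))), rep(0, 44),
               tolerance = 1e-12)
  expect_equal(unname(apply(as.matrix(split$train[f]), 2, sd)), rep(1, 44),
               tolerance = 1e-12)
  # validation/test are scaled by the same constants, not their own
  expect_false(all(abs(colMeans(as.matrix(split$test[f]))) < 1e-10))
})
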