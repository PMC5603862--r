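test_that("read_descriptor_table parses, validates and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,pIC50,a,b",
               "c1,5.1,0.1,1.0",
               "c2,6.2,0.4,2.0",
               "c3,7.3,0.9,3.0"), path)
  tbl <- read_descriptor_table(path)
  expect_equal(dim(tbl$X), c(3L, 2L))
  expect_equal(tbl$descriptor_names, c("a", "b"))
  expect_equal(tbl$compound_ids, c("c1", "c2", "c3"))
  expect_equal(tbl$y, c(5.1, 6.2, 7.3))

  # missing configured column
  expect_error(read_descriptor_table(path, activity_column = "IC90"),
               "configuration error.*IC90")

  # blank cell is a data error naming row and column
  writeLines(c("compound_id,pIC50,a,b",
               "c1,5.1,0.1,1.0",
               "c2,6.2,,2.0"), path)
  expect_error(read_descriptor_table(path), "data error.*row 2.*'a'")

  # generator -> CSV -> read-back round trip
  gen <- generate_synthetic_table(synthetic_spec(12, 6, 2, noise_sd = 0.3,
                                                 seed = 9))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(gen$table, p2)
  back <- read_descriptor_table(p2)
  expect_equal(back$X, gen$table$X, tolerance = 1e-12)
  expect_equal(back$y, gen$table$y, tolerance = 1e-12)
  expect_identical(back$compound_ids, gen$table$compound_ids)
  expect_identical(back$descriptor_names, gen$table$descriptor_names)
})

test_that("descriptor_table invariants are enforced", {
  X <- matrix(1:6, 3, 2)
  expect_error(descriptor_table(X, c(1, 2)), "length")
  expect_error(descriptor_table(X, 1:3, compound_ids = c("a", "a", "b")),
               "unique")
  X[1, 1] <- NA
  expect_error(descriptor_table(X, 1:3), "missing")
})

test_that("remove_constant_descriptors drops exactly the flat columns", {
  gen <- generate_synthetic_table(synthetic_spec(20, 12, 2, noise_sd = 0.1,
                                                 n_constant_cols = 3L, seed = 3))
  out <- remove_constant_descriptors(gen$table)
  expect_setequal(out$log$removed_constant, gen$truth$constant_names)
  expect_equal(ncol(out$table$X), 9L)
  expect_true(all(apply(out$table$X, 2, function(c) diff(range(c)) > 0)))

  # no constants: identity, empty log
  again <- remove_constant_descriptors(out$table)
  expect_identical(again$table$X, out$table$X)
  expect_length(again$log$removed_constant, 0L)

  # everything constant is unrecoverable
  flat <- descriptor_table(matrix(1, 4, 2), rnorm(4))
  expect_error(remove_constant_descriptors(flat), "data error")
})

test_that("correlation_filter matches the greedy all-pairs oracle", {
  # identical columns: r = 1, one dropped
  X <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 3, 2))
  out <- correlation_filter(descriptor_table(X, rnorm(4)))
  expect_equal(out$table$descriptor_names, c("a", "c"))
  expect_equal(out$log$removed_correlated[[1]]$kept, "a")
  expect_equal(out$log$removed_correlated[[1]]$dropped, "b")
  expect_equal(out$log$removed_correlated[[1]]$pearson_r, 1)

  # orthogonal columns survive untouched
  Xo <- cbind(x = c(1, 1, -1, -1), y = c(1, -1, 1, -1), z = c(1, -1, -1, 1))
  keep_all <- correlation_filter(descriptor_table(Xo, rnorm(4)))
  expect_equal(ncol(keep_all$table$X), 3L)

  expect_error(correlation_filter(descriptor_table(Xo, rnorm(4)), threshold = 1.2),
               "configuration error")

  # random tables vs the left-to-right greedy oracle, plus the all-pairs
  # post-condition, across sizes up to 20 columns
  for (seed in 1:5) {
    set.seed(seed)
    p <- sample(6:20, 1)
    base <- matrix(rnorm(10 * p), 10, p)
    # induce some correlation structure
    for (j in seq(2, p, by = 3)) base[, j] <- base[, j - 1] + rnorm(10, sd = 0.3)
    tbl <- descriptor_table(base, rnorm(10))
    out <- correlation_filter(tbl, 0.8)
    kept_oracle <- oracle_greedy_corr_filter(base, 0.8)
    expect_equal(out$table$descriptor_names, tbl$descriptor_names[kept_oracle])
    cm <- abs(stats::cor(out$table$X))
    diag(cm) <- 0
    expect_true(all(cm <= 0.8))
  }
})

test_that("preprocessing is idempotent", {
  gen <- generate_synthetic_table(synthetic_spec(30, 15, 2, noise_sd = 0.2,
                                                 n_constant_cols = 2L,
                                                 n_correlated_pairs = 2L, seed = 5))
  once <- preprocess_descriptors(gen$table)
  twice <- preprocess_descriptors(once$table)
  expect_identical(twice$table$X, once$table$X)
  expect_length(twice$log$removed_constant, 0L)
  expect_length(twice$log$removed_correlated, 0L)
})

test_that("y_rank_split partitions by systematic activity-rank sampling", {
  mk <- function(n, seed = 1) generate_synthetic_table(
    synthetic_spec(n, 6, 2, noise_sd = 0.5, seed = seed))$table

  sp55 <- y_rank_split(mk(55))
  expect_equal(nrow(sp55$train$X), 44L)
  expect_equal(nrow(sp55$test$X), 11L)

  sp45 <- y_rank_split(mk(45))
  expect_equal(nrow(sp45$train$X), 36L)
  expect_equal(nrow(sp45$test$X), 9L)

  # 5 compounds: the systematic rule picks exactly the activity median
  t5 <- mk(5)
  sp5 <- y_rank_split(t5)
  median_id <- t5$compound_ids[order(t5$y)][3]
  expect_identical(sp5$test$compound_ids, median_id)

  # partition + range overlap, across sizes
  for (n in c(20, 37, 55)) {
    tbl <- mk(n, seed = n)
    sp <- y_rank_split(tbl)
    expect_setequal(c(sp$train$compound_ids, sp$test$compound_ids),
                    tbl$compound_ids)
    expect_length(intersect(sp$train$compound_ids, sp$test$compound_ids), 0L)
    expect_true(min(sp$test$y) >= min(sp$train$y) - 1e-12 ||
                  max(sp$test$y) <= max(sp$train$y) + 1e-12)
    expect_lt(min(sp$test$y), max(sp$train$y))
    expect_gt(max(sp$test$y), min(sp$train$y))
  }

  expect_error(y_rank_split(mk(20), 0.7), "configuration error")
})

test_that("feature_budget floors at 20 percent and is monotone", {
  expect_equal(feature_budget(44), 8L)
  expect_equal(feature_budget(63), 12L)
  expect_equal(feature_budget(36), 7L)
  budgets <- vapply(5:120, feature_budget, integer(1))
  expect_true(all(diff(budgets) >= 0))
  expect_true(all(budgets >= 1L))
  expect_error(feature_budget(4), "data error")
})
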