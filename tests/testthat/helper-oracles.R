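# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force sums, dense solves, enumeration.

# Normal-equations OLS: beta = (D'D)^{-1} D'y with explicit intercept column.
oracle_ols <- function(X, y) {
  D <- cbind(1, as.matrix(X))
  drop(solve(crossprod(D), crossprod(D, y)))
}

# Exhaustive search over all weight-k subsets, fitting by the oracle OLS.
# Returns the minimum train RMSE and the minimizing index set.
oracle_exhaustive <- function(tbl, k) {
  p <- ncol(tbl$X)
  combs <- utils::combn(p, k)
  best <- Inf
  best_idx <- NULL
  for (i in seq_len(ncol(combs))) {
    idx <- combs[, i]
    D <- cbind(1, tbl$X[, idx, drop = FALSE])
    beta <- tryCatch(solve(crossprod(D), crossprod(D, tbl$y)),
                     error = function(e) NULL)
    if (is.null(beta)) next  # singular subset (e.g. planted constants)
    r <- sqrt(mean((tbl$y - drop(D %*% beta))^2))
    if (r < best) {
      best <- r
      best_idx <- idx
    }
  }
  list(rmse = best, idx = best_idx)
}

# Small deterministic table for unit tests: 8 compounds x 5 descriptors,
# exact linear signal on columns 1 and 3.
tiny_table <- function(noise_sd = 0, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(8 * 5), 8, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 + 1.5 * X[, 1] - 0.7 * X[, 3] + rnorm(8, sd = noise_sd)
  descriptor_table(X, y, compound_ids = paste0("m", 1:8))
}

# Greedy left-to-right correlation-filter oracle: walk columns in order,
# drop any column whose |r| with an already-kept column exceeds the threshold.
oracle_greedy_corr_filter <- function(X, threshold) {
  kept <- integer(0)
  for (j in seq_len(ncol(X))) {
    ok <- TRUE
    for (i in kept) {
      if (abs(stats::cor(X[, i], X[, j])) > threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, j)
  }
  kept
}

expect_weight <- function(genes, k) expect_equal(sum(genes), k)
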