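#' Specification for a synthetic descriptor table
#'
#' Describes a descriptor matrix with a planted linear signal: standard
#' normal descriptors, an activity built from a known `k_true`-subset plus
#' Gaussian noise, and optional planted pathologies (constant columns,
#' near-duplicate correlated pairs) that the preprocessing step must
#' remove. The activity intercept defaults to 6.68 so fixtures sit in a
#' realistic pIC50 range.
#'
#' @param n_compounds number of rows.
#' @param n_descriptors number of descriptor columns (including planted
#'   constants and correlated duplicates).
#' @param k_true size of the planted signal subset.
#' @param beta coefficient vector of length `k_true`; defaults to
#'   magnitudes decreasing from 1 to 0.5 with alternating signs.
#' @param intercept activity intercept.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param n_constant_cols number of planted constant columns.
#' @param n_correlated_pairs number of planted near-duplicate pairs
#'   (population correlation about 0.99; each pair occupies two columns,
#'   neither of which carries signal).
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds, n_descriptors, k_true,
                           beta = NULL, intercept = 6.68, noise_sd = 0,
                           n_constant_cols = 0L, n_correlated_pairs = 0L,
                           seed = 1L) {
  if (is.null(beta)) {
    beta <- seq(1, 0.5, length.out = k_true) *
      rep_len(c(1, -1), k_true)
  }
  if (length(beta) != k_true)
    stop("configuration error: length(beta) != k_true", call. = FALSE)
  if (k_true > n_descriptors - n_constant_cols - 2L * n_correlated_pairs)
    stop("configuration error: not enough free columns for the planted signal",
         call. = FALSE)
  if (noise_sd < 0)
    stop("configuration error: noise_sd must be >= 0", call. = FALSE)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 k_true = as.integer(k_true),
                 beta = as.numeric(beta), intercept = intercept,
                 noise_sd = noise_sd,
                 n_constant_cols = as.integer(n_constant_cols),
                 n_correlated_pairs = as.integer(n_correlated_pairs),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic descriptor table with known ground truth
#'
#' Column layout (all at known indices, recorded in the ground truth):
#' the first `k_true` columns carry the signal; then independent noise
#' columns; then `n_correlated_pairs` pairs of near-duplicate columns
#' (base + duplicate, sample correlation forced above 0.95); constant
#' columns last. `y = intercept + X[, true] %*% beta + N(0, noise_sd^2)`.
#' The same seed reproduces the table bit for bit.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (a [descriptor_table()]) and `truth`: a list
#'   holding `true_indices`, `true_names`, `beta`, `intercept`,
#'   `noise_sd`, `constant_names`, `correlated_pairs` (two-column
#'   character matrix base/duplicate), `seed`.
#' @export
generate_synthetic_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  p <- spec$n_descriptors
  k <- spec$k_true
  n_pair_cols <- 2L * spec$n_correlated_pairs
  n_free <- p - spec$n_constant_cols - n_pair_cols
  X <- matrix(0, n, p)
  X[, seq_len(n_free)] <- stats::rnorm(n * n_free)
  names_vec <- character(p)
  names_vec[seq_len(n_free)] <- paste0("D", sprintf("%03d", seq_len(n_free)))
  col <- n_free
  pair_names <- matrix(character(0), 0L, 2L,
                       dimnames = list(NULL, c("base", "duplicate")))
  for (q in seq_len(spec$n_correlated_pairs)) {
    base <- stats::rnorm(n)
    dup <- base + stats::rnorm(n, sd = 0.1)
    while (abs(stats::cor(base, dup)) < 0.95)   # enforce the stated r >= 0.95
      dup <- base + stats::rnorm(n, sd = 0.05)
    X[, col + 1L] <- base
    X[, col + 2L] <- dup
    names_vec[col + 1L] <- sprintf("CORA%02d", q)
    names_vec[col + 2L] <- sprintf("CORB%02d", q)
    pair_names <- rbind(pair_names, c(names_vec[col + 1L], names_vec[col + 2L]))
    col <- col + 2L
  }
  for (q in seq_len(spec$n_constant_cols)) {
    X[, col + q] <- q  # distinct constant levels, all zero-variance
    names_vec[col + q] <- sprintf("CONST%02d", q)
  }
  colnames(X) <- names_vec
  true_idx <- seq_len(k)
  y <- spec$intercept + drop(X[, true_idx, drop = FALSE] %*% spec$beta) +
    stats::rnorm(n, sd = spec$noise_sd)
  tbl <- descriptor_table(X, y, compound_ids = paste0("cmp", sprintf("%03d", seq_len(n))))
  truth <- list(true_indices = true_idx,
                true_names = names_vec[true_idx],
                beta = spec$beta, intercept = spec$intercept,
                noise_sd = spec$noise_sd,
                constant_names = names_vec[grepl("^CONST", names_vec)],
                correlated_pairs = pair_names,
                seed = spec$seed)
  list(table = tbl, truth = truth)
}

#' Write the canonical synthetic fixture suite
#'
#' Generates three reduced-scale tables whose shapes mirror typical QSAR
#' benchmark sets (55, 79 and 45 compounds with descriptor counts scaled
#' down to keep exhaustive subset enumeration cheap), each with a planted
#' k = 3 signal, mild noise, two constant columns and two correlated
#' pairs. Each table is written as CSV next to a ground-truth JSON.
#'
#' @param out_dir writable output directory (created if missing).
#' @return character vector of the file paths written.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    qsar55x40 = synthetic_spec(55, 40, 3, noise_sd = 0.1,
                               n_constant_cols = 2L, n_correlated_pairs = 2L,
                               seed = 101L),
    qsar79x48 = synthetic_spec(79, 48, 3, noise_sd = 0.1,
                               n_constant_cols = 2L, n_correlated_pairs = 2L,
                               seed = 102L),
    qsar45x24 = synthetic_spec(45, 24, 3, noise_sd = 0.1,
                               n_constant_cols = 2L, n_correlated_pairs = 2L,
                               seed = 103L))
  paths <- character(0)
  for (nm in names(specs)) {
    gen <- generate_synthetic_table(specs[[nm]])
    csv <- file.path(out_dir, paste0(nm, ".csv"))
    js <- file.path(out_dir, paste0(nm, "_truth.json"))
    write_descriptor_table(gen$table, csv)
    truth <- gen$truth
    truth$correlated_pairs <- apply(truth$correlated_pairs, 1L, identity,
                                    simplify = FALSE)
    jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, csv, js)
  }
  paths
}
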