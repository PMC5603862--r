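#' Remove constant descriptors
#'
#' Descriptors whose value is identical across all compounds carry no
#' information for regression and make the Pearson correlation undefined;
#' they are dropped before any selection is attempted.
#'
#' @param tbl a [descriptor_table()].
#' @return A list with elements `table` (the filtered `descriptor_table`)
#'   and `log` (a `preprocess_log`, see [preprocess_log()]).
#' @export
remove_constant_descriptors <- function(tbl) {
  tbl <- validate_descriptor_table(tbl)
  is_const <- apply(tbl$X, 2L, function(col) diff(range(col)) == 0)
  if (all(is_const))
    stop("data error: all descriptor columns are constant; nothing to select",
         call. = FALSE)
  dropped <- tbl$descriptor_names[is_const]
  out <- tbl
  if (any(is_const)) {
    out <- descriptor_table(tbl$X[, !is_const, drop = FALSE], tbl$y,
                            compound_ids = tbl$compound_ids,
                            descriptor_names = tbl$descriptor_names[!is_const])
  }
  list(table = out, log = preprocess_log(removed_constant = dropped))
}

#' Filter inter-correlated descriptor pairs
#'
#' Any pair of surviving descriptors with absolute Pearson correlation
#' strictly greater than `threshold` is considered inter-correlated and only
#' one member is retained. Columns are scanned left to right; a column is
#' dropped if it correlates above the threshold with any already-kept
#' column (keep-first rule, deterministic).
#'
#' @param tbl a [descriptor_table()] with no constant columns.
#' @param threshold absolute Pearson correlation above which a pair is
#'   inter-correlated; default 0.80.
#' @return A list with `table` and `log` as in
#'   [remove_constant_descriptors()]; the log's `removed_correlated` holds
#'   one `(kept, dropped, r)` record per dropped column.
#' @export
correlation_filter <- function(tbl, threshold = 0.80) {
  tbl <- validate_descriptor_table(tbl)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("configuration error: threshold must lie in (0, 1]", call. = FALSE)
  p <- ncol(tbl$X)
  cm <- suppressWarnings(stats::cor(tbl$X))
  if (anyNA(cm))
    stop("data error: constant column present; run remove_constant_descriptors first",
         call. = FALSE)
  keep <- logical(p)
  removed <- list()
  for (j in seq_len(p)) {
    kept_idx <- which(keep)
    r_with_kept <- if (length(kept_idx)) abs(cm[j, kept_idx]) else numeric(0)
    offender <- which(r_with_kept > threshold)
    if (length(offender) == 0L) {
      keep[j] <- TRUE
    } else {
      culprit <- kept_idx[offender[1L]]
      removed[[length(removed) + 1L]] <- list(
        kept = tbl$descriptor_names[culprit],
        dropped = tbl$descriptor_names[j],
        pearson_r = unname(cm[j, culprit]))
    }
  }
  out <- tbl
  if (!all(keep)) {
    out <- descriptor_table(tbl$X[, keep, drop = FALSE], tbl$y,
                            compound_ids = tbl$compound_ids,
                            descriptor_names = tbl$descriptor_names[keep])
  }
  list(table = out, log = preprocess_log(removed_correlated = removed))
}

#' Preprocessing log
#'
#' Records which descriptors were discarded and why; serialize with
#' [write_preprocess_log()] next to experiment outputs.
#'
#' @param removed_constant character vector of constant descriptor names.
#' @param removed_correlated list of `(kept, dropped, pearson_r)` records.
#' @return An object of class `preprocess_log`.
#' @export
preprocess_log <- function(removed_constant = character(0),
                           removed_correlated = list()) {
  structure(list(removed_constant = as.character(removed_constant),
                 removed_correlated = removed_correlated),
            class = "preprocess_log")
}

#' @export
print.preprocess_log <- function(x, ...) {
  cat(sprintf("preprocess_log: %d constant, %d inter-correlated descriptors removed\n",
              length(x$removed_constant), length(x$removed_correlated)))
  invisible(x)
}

merge_preprocess_logs <- function(a, b) {
  preprocess_log(removed_constant = c(a$removed_constant, b$removed_constant),
                 removed_correlated = c(a$removed_correlated, b$removed_correlated))
}

#' Serialize a preprocess log to JSON
#' @param log a `preprocess_log`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_preprocess_log <- function(log, path) {
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Full descriptor preprocessing
#'
#' Convenience wrapper: constant-column removal followed by the Pearson
#' correlation filter. Idempotent: applying it twice gives the same table.
#'
#' @inheritParams correlation_filter
#' @return list with `table` and the merged `log`.
#' @export
preprocess_descriptors <- function(tbl, threshold = 0.80) {
  s1 <- remove_constant_descriptors(tbl)
  s2 <- correlation_filter(s1$table, threshold = threshold)
  list(table = s2$table, log = merge_preprocess_logs(s1$log, s2$log))
}

#' Activity-ranked train/test split
#'
#' Splits compounds by systematic sampling over the activity ranking
#' ("Y-ranking"): compounds are sorted by activity and every m-th compound
#' (m = `round(1 / test_fraction)`, starting at offset `ceiling(m / 2)`) is
#' assigned to the test set. Both sets therefore span the whole activity
#' range, which is what external validation statistics assume.
#'
#' @param tbl a [descriptor_table()] with at least 5 compounds.
#' @param test_fraction fraction of compounds held out, in (0, 0.5];
#'   default 0.2.
#' @return An object of class `split_dataset` with fields `train`, `test`
#'   (both `descriptor_table`) and `test_fraction`.
#' @examples
#' tbl <- generate_synthetic_table(synthetic_spec(n_compounds = 55,
#'   n_descriptors = 10, k_true = 2, seed = 1))$table
#' sp <- y_rank_split(tbl)
#' c(train = nrow(sp$train$X), test = nrow(sp$test$X))  # 44 / 11
#' @export
y_rank_split <- function(tbl, test_fraction = 0.2) {
  tbl <- validate_descriptor_table(tbl)
  n <- nrow(tbl$X)
  if (n < 5L) stop("data error: need at least 5 compounds", call. = FALSE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction > 0.5)
    stop("configuration error: test_fraction must lie in (0, 0.5]", call. = FALSE)
  m <- max(2L, as.integer(round(1 / test_fraction)))
  ord <- order(tbl$y, tbl$compound_ids)  # ties broken by id for determinism
  start <- as.integer(ceiling(m / 2))
  test_ranks <- seq.int(start, n, by = m)
  test_rows <- ord[test_ranks]
  train_rows <- setdiff(ord, test_rows)
  structure(list(train = subset_compounds(tbl, train_rows),
                 test = subset_compounds(tbl, test_rows),
                 test_fraction = test_fraction),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("split_dataset: %d train / %d test compounds (fraction %.2f)\n",
              nrow(x$train$X), nrow(x$test$X), x$test_fraction))
  invisible(x)
}

#' Feature budget from training-set size
#'
#' The selectors search for subsets of a fixed size: 20 percent of the
#' number of training compounds (rounded down, minimum 1). This keeps the
#' sample-to-feature ratio at the conventional 5:1.
#'
#' @param n_train number of training compounds (>= 5).
#' @param fraction budget fraction; default 0.2.
#' @return integer subset size `k`.
#' @examples
#' feature_budget(44)  # 8
#' feature_budget(63)  # 12
#' feature_budget(36)  # 7
#' @export
feature_budget <- function(n_train, fraction = 0.2) {
  if (n_train < 5L) stop("data error: n_train must be >= 5", call. = FALSE)
  max(1L, as.integer(floor(fraction * n_train)))
}
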