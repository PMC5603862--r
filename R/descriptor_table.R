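#' Construct a descriptor table
#'
#' The basic container for a QSAR dataset: a numeric matrix of molecular
#' descriptors (rows = compounds, columns = descriptors) together with the
#' observed activity vector (typically pIC50). All selectors and evaluators
#' in the package operate on this object.
#'
#' @param X numeric matrix, `n_compounds x n_descriptors`. Column names are
#'   taken as descriptor names unless `descriptor_names` is given.
#' @param y numeric activity vector, length `nrow(X)`.
#' @param compound_ids character vector of unique compound identifiers.
#' @param descriptor_names character vector of unique descriptor names.
#' @return An object of class `descriptor_table` with fields `X`, `y`,
#'   `compound_ids`, `descriptor_names`.
#' @examples
#' X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("MW", "nAtoms", "logP")))
#' dt <- descriptor_table(X, y = rnorm(4), compound_ids = paste0("c", 1:4))
#' dt
#' @export
descriptor_table <- function(X, y, compound_ids = NULL, descriptor_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(descriptor_names)) descriptor_names <- colnames(X)
  if (is.null(descriptor_names)) descriptor_names <- paste0("d", seq_len(ncol(X)))
  if (is.null(compound_ids)) compound_ids <- paste0("cmp", seq_len(nrow(X)))
  compound_ids <- as.character(compound_ids)
  descriptor_names <- as.character(descriptor_names)
  y <- as.numeric(y)
  obj <- structure(
    list(X = X, y = y, compound_ids = compound_ids,
         descriptor_names = descriptor_names),
    class = "descriptor_table")
  validate_descriptor_table(obj)
}

validate_descriptor_table <- function(tbl) {
  stopifnot(inherits(tbl, "descriptor_table"))
  if (nrow(tbl$X) != length(tbl$y))
    stop("descriptor_table: nrow(X) != length(y)", call. = FALSE)
  if (nrow(tbl$X) != length(tbl$compound_ids))
    stop("descriptor_table: nrow(X) != length(compound_ids)", call. = FALSE)
  if (ncol(tbl$X) != length(tbl$descriptor_names))
    stop("descriptor_table: ncol(X) != length(descriptor_names)", call. = FALSE)
  if (anyDuplicated(tbl$compound_ids))
    stop("descriptor_table: compound ids must be unique", call. = FALSE)
  if (anyDuplicated(tbl$descriptor_names))
    stop("descriptor_table: descriptor names must be unique", call. = FALSE)
  if (anyNA(tbl$X) || any(!is.finite(tbl$X)))
    stop("descriptor_table: X contains missing or non-finite values", call. = FALSE)
  if (anyNA(tbl$y) || any(!is.finite(tbl$y)))
    stop("descriptor_table: y contains missing or non-finite values", call. = FALSE)
  colnames(tbl$X) <- tbl$descriptor_names
  tbl
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("descriptor_table: %d compounds x %d descriptors\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  activity range: [%.3g, %.3g], mean %.3g\n",
              min(x$y), max(x$y), mean(x$y)))
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$X)

#' Subset a descriptor table by compound rows
#' @param tbl a `descriptor_table`.
#' @param rows integer or logical row index.
#' @return a `descriptor_table` restricted to `rows`.
#' @keywords internal
subset_compounds <- function(tbl, rows) {
  descriptor_table(tbl$X[rows, , drop = FALSE], tbl$y[rows],
                   compound_ids = tbl$compound_ids[rows],
                   descriptor_names = tbl$descriptor_names)
}

#' Read a descriptor table from CSV
#'
#' Expects a comma-separated file with a header row, one compound-identifier
#' column, one activity column, and any number of numeric descriptor
#' columns. The descriptor order of the file is preserved.
#'
#' @param path CSV file path.
#' @param activity_column name of the activity column (e.g. `"pIC50"`).
#' @param id_column name of the compound-identifier column.
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path, activity_column = "pIC50",
                                  id_column = "compound_id") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(id_column, activity_column)) {
    if (!col %in% names(df))
      stop(sprintf("configuration error: column '%s' not present in %s",
                   col, path), call. = FALSE)
  }
  desc_cols <- setdiff(names(df), c(id_column, activity_column))
  if (length(desc_cols) == 0L)
    stop("data error: no descriptor columns in ", path, call. = FALSE)
  X <- matrix(NA_real_, nrow(df), length(desc_cols),
              dimnames = list(NULL, desc_cols))
  for (j in seq_along(desc_cols)) {
    v <- df[[desc_cols[j]]]
    if (is.character(v)) v[v == ""] <- NA
    v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L)
      stop(sprintf("data error: non-numeric or missing value at row %d, column '%s'",
                   bad[1L], desc_cols[j]), call. = FALSE)
    X[, j] <- v
  }
  y <- suppressWarnings(as.numeric(df[[activity_column]]))
  bad <- which(is.na(y) | !is.finite(y))
  if (length(bad) > 0L)
    stop(sprintf("data error: non-numeric or missing value at row %d, column '%s'",
                 bad[1L], activity_column), call. = FALSE)
  descriptor_table(X, y, compound_ids = df[[id_column]],
                   descriptor_names = desc_cols)
}

#' Write a descriptor table to CSV
#'
#' Inverse of [read_descriptor_table()]; round-trips exactly up to numeric
#' print precision (15 significant digits are written).
#'
#' @param tbl a `descriptor_table`.
#' @param path output CSV path.
#' @param activity_column,id_column column names to use in the header.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(tbl, path, activity_column = "pIC50",
                                   id_column = "compound_id") {
  df <- data.frame(tbl$compound_ids, tbl$y, tbl$X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, activity_column, tbl$descriptor_names)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
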