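#' External-validation statistics (Golbraikh-Tropsha / Roy criteria)
#'
#' Computes the standard external test-set statistics for a QSAR model and
#' evaluates the five pass/fail criteria:
#' \describe{
#'   \item{R4}{cross-validated `Q2 > 0.5` (supplied by the caller, see
#'     [loocv_q2()]);}
#'   \item{R5}{`rp2 > 0.6`, the squared Pearson correlation of observed vs
#'     predicted;}
#'   \item{R6}{`(rp2 - r0p2)/rp2 < 0.1` or `(rp2 - r0p2')/rp2 < 0.1`,
#'     where `r0p2` / `r0p2'` are the through-origin determination
#'     coefficients (observed-on-predicted and predicted-on-observed);}
#'   \item{R7}{`0.85 <= k <= 1.15` or `0.85 <= k' <= 1.15`, the
#'     through-origin regression slopes;}
#'   \item{R8}{`rm2 > 0.5` and `rm2' > 0.5`, with
#'     `rm2 = rp2 (1 - sqrt(rp2 - r0p2))`.}
#' }
#' A negative radicand in `rm2` (possible when `r0p2 > rp2`) is clamped to
#' zero and flagged in `clamped`.
#'
#' @param y_obs_test,y_pred_test observed and predicted activities of the
#'   external test set (length >= 3).
#' @param q2_train cross-validated determination coefficient of the
#'   training model.
#' @return object of class `validation_report` with the statistics and a
#'   named logical `passes` map (`R4`..`R8`, `all`).
#' @export
tropsha_roy_stats <- function(y_obs_test, y_pred_test, q2_train) {
  y <- as.numeric(y_obs_test)
  yh <- as.numeric(y_pred_test)
  if (length(y) != length(yh) || length(y) < 3L)
    stop("data error: need equal-length vectors of at least 3 points",
         call. = FALSE)
  rp2 <- squared_pearson(y, yh)
  k <- sum(y * yh) / sum(yh^2)
  k_prime <- sum(y * yh) / sum(y^2)
  # through-origin determination coefficient of a regressed on b
  r0_sq <- function(a, b) {
    slope <- sum(a * b) / sum(b^2)
    1 - sum((a - slope * b)^2) / sum((a - mean(a))^2)
  }
  r0p2 <- r0_sq(y, yh)        # observed on predicted
  r0p2_prime <- r0_sq(yh, y)  # predicted on observed
  clamped <- c(rm2 = rp2 - r0p2 < 0, rm2_prime = rp2 - r0p2_prime < 0)
  rm2 <- rp2 * (1 - sqrt(max(0, rp2 - r0p2)))
  rm2_prime <- rp2 * (1 - sqrt(max(0, rp2 - r0p2_prime)))
  delta <- (rp2 - r0p2) / rp2
  delta_prime <- (rp2 - r0p2_prime) / rp2
  passes <- c(R4 = q2_train > 0.5,
              R5 = rp2 > 0.6,
              R6 = delta < 0.1 || delta_prime < 0.1,
              R7 = (k >= 0.85 && k <= 1.15) || (k_prime >= 0.85 && k_prime <= 1.15),
              R8 = rm2 > 0.5 && rm2_prime > 0.5)
  passes <- c(passes, all = all(passes))
  structure(list(q2 = q2_train, rp2 = rp2, r0p2 = r0p2,
                 r0p2_prime = r0p2_prime, rm2 = rm2, rm2_prime = rm2_prime,
                 k = k, k_prime = k_prime,
                 deltas = c(delta = delta, delta_prime = delta_prime),
                 clamped = clamped, passes = passes),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("external validation report\n")
  cat(sprintf("  Q2 = %.3f  rp2 = %.3f  r0p2 = %.3f  r'0p2 = %.3f\n",
              x$q2, x$rp2, x$r0p2, x$r0p2_prime))
  cat(sprintf("  rm2 = %.3f  r'm2 = %.3f  k = %.3f  k' = %.3f\n",
              x$rm2, x$rm2_prime, x$k, x$k_prime))
  status <- ifelse(x$passes[c("R4", "R5", "R6", "R7", "R8")], "pass", "FAIL")
  cat("  criteria:", paste(sprintf("%s=%s", c("R4", "R5", "R6", "R7", "R8"),
                                   status), collapse = "  "), "\n")
  invisible(x)
}

#' Leave-one-out Q-squared
#'
#' `Q2 = 1 - PRESS / SS_total` on the training set: the determination
#' coefficient of leave-one-out predictions against the training mean.
#'
#' @param y_obs observed training activities.
#' @param y_loo_pred leave-one-out predicted activities.
#' @return scalar Q2 (<= 1; can be negative for models worse than the mean).
#' @export
loocv_q2 <- function(y_obs, y_loo_pred) {
  if (length(y_obs) != length(y_loo_pred))
    stop("data error: lengths differ", call. = FALSE)
  1 - sum((y_obs - y_loo_pred)^2) / sum((y_obs - mean(y_obs))^2)
}

#' Leave-one-out predictions for an LS-SVR specification
#'
#' Explicit per-fold refit; used for the Q2 of a final model report.
#'
#' @param X training design (selected descriptors).
#' @param y activity vector.
#' @param gamma,sigma2 LS-SVR hyperparameters.
#' @return numeric vector of held-out predictions.
#' @export
lssvr_loo_predictions <- function(X, y, gamma, sigma2) {
  X <- as.matrix(X)
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    m <- fit_lssvr(X[-i, , drop = FALSE], y[-i], gamma, sigma2)
    predict(m, X[i, , drop = FALSE])
  }, numeric(1))
}

#' Applicability-domain assessment (Williams plot data)
#'
#' Leverages are the diagonal of the hat matrix of the selected training
#' descriptors, `h_i = x_i (X'X)^{-1} x_i'` (no intercept column; the
#' selected descriptor count is the model parameter count `p`). The
#' warning threshold is `h* = 3 p / n`. Standardized residuals are scaled
#' by the training residual standard deviation; compounds with
#' `|std residual| > 3` or leverage above `h*` are flagged as outside the
#' domain.
#'
#' @param X_train_selected,X_test_selected selected-descriptor designs.
#' @param residuals_train,residuals_test model residuals (observed minus
#'   predicted).
#' @param train_ids,test_ids optional compound identifiers for the outlier
#'   report.
#' @return object of class `ad_report` with `leverages_train`,
#'   `leverages_test`, `h_star`, `std_residuals_train`,
#'   `std_residuals_test`, `outliers` (ids), and a `williams` data frame
#'   (`compound_id`, `leverage`, `std_residual`, `set`).
#' @export
applicability_domain <- function(X_train_selected, X_test_selected,
                                 residuals_train, residuals_test,
                                 train_ids = NULL, test_ids = NULL) {
  Xtr <- as.matrix(X_train_selected)
  Xte <- as.matrix(X_test_selected)
  p <- ncol(Xtr)
  n <- nrow(Xtr)
  if (is.null(train_ids)) train_ids <- paste0("train", seq_len(n))
  if (is.null(test_ids)) test_ids <- paste0("test", seq_len(nrow(Xte)))
  XtX <- crossprod(Xtr)
  XtX_inv <- tryCatch(solve(XtX), error = function(e) {
    warning("X'X singular; using pseudo-inverse for leverages")
    pseudo_inverse(XtX)
  })
  lev <- function(M) rowSums((M %*% XtX_inv) * M)
  h_train <- lev(Xtr)
  h_test <- lev(Xte)
  h_star <- 3 * p / n
  s <- stats::sd(residuals_train)
  std_train <- residuals_train / s
  std_test <- residuals_test / s
  out_train <- train_ids[abs(std_train) > 3 | h_train > h_star]
  out_test <- test_ids[abs(std_test) > 3 | h_test > h_star]
  williams <- data.frame(
    compound_id = c(train_ids, test_ids),
    leverage = c(h_train, h_test),
    std_residual = c(std_train, std_test),
    set = rep(c("train", "test"), c(n, nrow(Xte))),
    stringsAsFactors = FALSE)
  structure(list(leverages_train = h_train, leverages_test = h_test,
                 h_star = h_star,
                 std_residuals_train = std_train,
                 std_residuals_test = std_test,
                 outliers = c(out_train, out_test),
                 williams = williams),
            class = "ad_report")
}

pseudo_inverse <- function(M) {
  sv <- svd(M)
  pos <- sv$d > max(dim(M)) * .Machine$double.eps * sv$d[1L]
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("applicability domain: h* = %.3f, %d/%d compounds outside\n",
              x$h_star, length(x$outliers), nrow(x$williams)))
  invisible(x)
}

#' Export Williams-plot data to CSV
#' @param report an `ad_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_williams_csv <- function(report, path) {
  utils::write.csv(report$williams, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a validation report to JSON
#' @param report a `validation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  out <- unclass(report)
  out$passes <- as.list(report$passes)
  out$clamped <- as.list(report$clamped)
  out$deltas <- as.list(report$deltas)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
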