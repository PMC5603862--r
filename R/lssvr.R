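#' RBF (Gaussian) kernel matrix
#'
#' `K[i, j] = exp(-||a_i - b_j||^2 / sigma2)`. The exponent convention is
#' `d^2 / sigma2` (not `2 sigma^2`), matching the LS-SVMlab toolbox.
#' Larger `sigma2` flattens the Gaussian and smooths the regression
#' surface.
#'
#' @param A,B numeric matrices with the same number of columns.
#' @param sigma2 kernel width parameter, > 0.
#' @return `nrow(A) x nrow(B)` kernel matrix.
#' @export
rbf_kernel <- function(A, B, sigma2) {
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stop("configuration error: sigma2 must be > 0", call. = FALSE)
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("data error: column counts differ", call. = FALSE)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  exp(-d2 / sigma2)
}

#' Fit a least-squares support vector regression
#'
#' Solves the LS-SVM dual system
#' `[[0, 1'], [1, K + I/gamma]] [bias; alpha] = [0; y]`
#' with an RBF kernel, via the standard two-solve reduction: with
#' `A = K + I/gamma`, `nu = A^{-1} 1`, `eta = A^{-1} y`, the bias is
#' `sum(eta) / sum(nu)` and `alpha = eta - bias * nu`. Training residuals
#' satisfy `y - yhat = alpha / gamma`.
#'
#' @param X training design (selected descriptors).
#' @param y activity vector.
#' @param gamma regularization parameter, > 0 (larger = less
#'   regularization).
#' @param sigma2 RBF kernel width, > 0.
#' @return object of class `lssvr_model` with `alpha`, `bias`, `gamma`,
#'   `sigma2`, `X_train`.
#' @export
fit_lssvr <- function(X, y, gamma, sigma2) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("data error: need at least 3 training rows", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0)
    stop("configuration error: gamma must be > 0", call. = FALSE)
  n <- nrow(X)
  A <- rbf_kernel(X, X, sigma2) + diag(1 / gamma, n)
  sol <- tryCatch(solve(A, cbind(1, y)),
                  error = function(e)
                    stop(sprintf("numerical error: dual system singular (rcond ~ %.3g)",
                                 rcond(A)), call. = FALSE))
  nu <- sol[, 1L]
  eta <- sol[, 2L]
  bias <- sum(eta) / sum(nu)
  alpha <- eta - bias * nu
  structure(list(alpha = alpha, bias = bias, gamma = gamma, sigma2 = sigma2,
                 X_train = X),
            class = "lssvr_model")
}

#' @export
print.lssvr_model <- function(x, ...) {
  cat(sprintf("lssvr_model: n = %d, gamma = %.4g, sigma2 = %.4g\n",
              nrow(x$X_train), x$gamma, x$sigma2))
  invisible(x)
}

#' Predict from a fitted LS-SVR model
#' @param object an `lssvr_model`.
#' @param newdata matrix with the columns the model was fitted on;
#'   defaults to the training design.
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
predict.lssvr_model <- function(object, newdata = object$X_train, ...) {
  K <- rbf_kernel(as.matrix(newdata), object$X_train, object$sigma2)
  drop(K %*% object$alpha) + object$bias
}

#' Grid search for LS-SVR hyperparameters
#'
#' Evaluates every `(gamma, sigma2)` pair of the grid by leave-one-out
#' cross-validated RMSE on the training set and returns the minimizer.
#' Ties are broken toward smaller `gamma`, then smaller `sigma2`. Default
#' grids span four decades of `gamma` and five of `sigma2`, wide enough to
#' bracket typical QSAR fits.
#'
#' @param train a [descriptor_table()].
#' @param subset logical mask or integer indices of the descriptors to use.
#' @param gamma_grid,sigma2_grid numeric vectors of candidate values.
#' @return list with `gamma`, `sigma2`, `cv_rmse`, and the full `grid`
#'   data frame.
#' @export
grid_search_lssvr <- function(train, subset,
                              gamma_grid = 10^seq(0, 4, length.out = 25),
                              sigma2_grid = 10^seq(-1, 4, length.out = 25)) {
  if (length(gamma_grid) < 1L || length(sigma2_grid) < 1L)
    stop("configuration error: empty hyperparameter grid", call. = FALSE)
  mask <- as_mask(subset, ncol(train$X))
  X <- train$X[, mask, drop = FALSE]
  y <- train$y
  grid <- expand.grid(gamma = sort(gamma_grid), sigma2 = sort(sigma2_grid))
  grid <- grid[order(grid$gamma, grid$sigma2), ]
  grid$cv_rmse <- vapply(seq_len(nrow(grid)), function(i)
    lssvr_loocv_rmse(X, y, grid$gamma[i], grid$sigma2[i]), numeric(1))
  best <- which.min(grid$cv_rmse)  # which.min takes the first: smallest gamma/sigma2
  list(gamma = grid$gamma[best], sigma2 = grid$sigma2[best],
       cv_rmse = grid$cv_rmse[best], grid = grid)
}

# Exact LS-SVM leave-one-out residuals from the inverse of the full
# bordered system: e_loo,i = alpha_i / C^{-1}_{ii} where C is the dual
# system matrix (standard result; avoids n refits per grid point).
lssvr_loocv_rmse <- function(X, y, gamma, sigma2) {
  n <- nrow(X)
  C <- rbind(c(0, rep(1, n)),
             cbind(1, rbf_kernel(X, X, sigma2) + diag(1 / gamma, n)))
  Cinv <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(Cinv)) return(Inf)
  sol <- Cinv %*% c(0, y)
  alpha <- sol[-1L]
  diag_inv <- diag(Cinv)[-1L]
  sqrt(mean((alpha / diag_inv)^2))
}
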