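#' Fit multiple linear regression with intercept
#'
#' Ordinary least squares on the selected descriptor columns. A
#' rank-deficient design (which occurs transiently during subset search
#' when correlated descriptors co-occur) is solved by the minimum-norm
#' least-squares solution via the SVD pseudo-inverse rather than raising.
#'
#' @param X_selected numeric matrix of the selected descriptors.
#' @param y activity vector.
#' @return An object of class `mlr_model` with `intercept` and
#'   `coefficients` (aligned with the columns of `X_selected`).
#' @export
fit_mlr <- function(X_selected, y) {
  X_selected <- as.matrix(X_selected)
  if (nrow(X_selected) < 2L)
    stop("data error: need at least 2 rows to fit", call. = FALSE)
  if (nrow(X_selected) != length(y))
    stop("data error: X and y are not aligned", call. = FALSE)
  D <- cbind(`(Intercept)` = 1, X_selected)
  fit <- stats::lm.fit(D, y)
  beta <- fit$coefficients
  if (anyNA(beta)) {            # rank deficient: minimum-norm solution
    sv <- svd(D)
    pos <- sv$d > max(dim(D)) * .Machine$double.eps * sv$d[1L]
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- drop(beta)
  }
  structure(list(intercept = unname(beta[1L]),
                 coefficients = unname(beta[-1L])),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("mlr_model: intercept %.4g, %d coefficients\n",
              x$intercept, length(x$coefficients)))
  invisible(x)
}

#' Predict from a fitted MLR model
#' @param object an `mlr_model`.
#' @param newdata matrix with the same columns the model was fitted on.
#' @param ... ignored.
#' @return numeric vector of predicted activities.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients) + object$intercept
}

#' Root-mean-square error
#'
#' `sqrt(sum((observed - predicted)^2) / M)` over the `M` evaluated
#' molecules; the fitness the selectors minimize.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return non-negative scalar in activity units.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("data error: observed and predicted lengths differ", call. = FALSE)
  if (length(observed) < 1L) stop("data error: empty vectors", call. = FALSE)
  sqrt(sum((observed - predicted)^2) / length(observed))
}

squared_pearson <- function(obs, pred) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
  stats::cor(obs, pred)^2
}

#' Fitness value container
#' @param rmse_value non-negative RMSE.
#' @param r2 squared Pearson correlation of observed vs predicted.
#' @param M number of molecules evaluated.
#' @return object of class `fitness_value`.
#' @keywords internal
fitness_value <- function(rmse_value, r2, M) {
  structure(list(rmse = rmse_value, r2 = r2, M = as.integer(M)),
            class = "fitness_value")
}

#' Evaluate a candidate descriptor subset
#'
#' Refits an MLR model on the training rows restricted to the subset and
#' scores it. `train_rmse` fits and scores on the same rows (the default
#' fitness inside the optimizers); `loocv_rmse` predicts each compound
#' from a model fitted on the remaining M-1 compounds (leave-one-out).
#' The LOO residuals are obtained with the exact hat-matrix identity
#' `e_loo = e / (1 - h)`; rows with leverage numerically 1 fall back to an
#' explicit refit.
#'
#' @param train a [descriptor_table()] (the training set).
#' @param subset logical mask over descriptors, or integer indices.
#' @param mode `"train_rmse"` or `"loocv_rmse"`.
#' @return a `fitness_value` with fields `rmse`, `r2`, `M`.
#' @export
evaluate_subset <- function(train, subset, mode = c("train_rmse", "loocv_rmse")) {
  mode <- match.arg(mode)
  mask <- as_mask(subset, ncol(train$X))
  k <- sum(mask)
  if (k < 1L) stop("domain error: empty descriptor subset", call. = FALSE)
  M <- nrow(train$X)
  Xs <- train$X[, mask, drop = FALSE]
  y <- train$y
  if (mode == "train_rmse") {
    model <- fit_mlr(Xs, y)
    pred <- predict(model, Xs)
  } else {
    if (k >= M - 1L)
      stop("domain error: k >= M - 1; LOOCV not identifiable", call. = FALSE)
    pred <- loo_predictions(Xs, y)
  }
  fitness_value(rmse(y, pred), squared_pearson(y, pred), M)
}

# Exact OLS leave-one-out predictions via the hat matrix.
loo_predictions <- function(Xs, y) {
  D <- cbind(1, Xs)
  qrD <- qr(D)
  h <- rowSums(qr.Q(qrD)[, seq_len(qrD$rank), drop = FALSE]^2)
  fit <- qr.fitted(qrD, y)
  e <- y - fit
  loo <- y - e / (1 - h)
  degenerate <- which(1 - h < 1e-10)
  for (i in degenerate) {
    m <- fit_mlr(Xs[-i, , drop = FALSE], y[-i])
    loo[i] <- predict(m, Xs[i, , drop = FALSE])
  }
  loo
}

#' @export
print.fitness_value <- function(x, ...) {
  cat(sprintf("fitness: rmse %.5g, r2 %.4f (M = %d)\n", x$rmse, x$r2, x$M))
  invisible(x)
}

as_mask <- function(subset, n) {
  if (is.logical(subset)) {
    if (length(subset) != n)
      stop("domain error: mask length != number of descriptors", call. = FALSE)
    return(subset)
  }
  mask <- logical(n)
  mask[as.integer(subset)] <- TRUE
  mask
}

# Fast fitness closure used by the search loops: mask -> list(rmse, r2).
# Avoids reconstructing descriptor_table objects in the hot path.
make_fitness <- function(train, mode = "train_rmse") {
  force(train)
  X <- train$X
  y <- train$y
  if (mode == "train_rmse") {
    function(mask) {
      D <- cbind(1, X[, mask, drop = FALSE])
      fit <- stats::lm.fit(D, y)
      beta <- fit$coefficients
      if (anyNA(beta)) {
        fv <- evaluate_subset(train, mask, "train_rmse")
        return(list(rmse = fv$rmse, r2 = fv$r2))
      }
      pred <- drop(D %*% beta)
      list(rmse = sqrt(sum((y - pred)^2) / length(y)),
           r2 = squared_pearson(y, pred))
    }
  } else {
    function(mask) {
      fv <- evaluate_subset(train, mask, "loocv_rmse")
      list(rmse = fv$rmse, r2 = fv$r2)
    }
  }
}
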