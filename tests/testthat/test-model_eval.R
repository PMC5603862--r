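test_that("rbf_kernel matches the elementwise distance oracle", {
  set.seed(301)
  A <- matrix(rnorm(15), 5, 3)
  B <- matrix(rnorm(9), 3, 3)
  K <- rbf_kernel(A, B, sigma2 = 2.5)
  for (i in 1:5) for (j in 1:3) {
    expect_equal(K[i, j], exp(-sum((A[i, ] - B[j, ])^2) / 2.5),
                 tolerance = 1e-12)
  }
  # identical rows -> 1; huge sigma2 flattens everything toward 1
  expect_equal(rbf_kernel(A[1, , drop = FALSE], A[1, , drop = FALSE], 1)[1, 1], 1)
  expect_true(all(abs(rbf_kernel(A, B, 1e12) - 1) < 1e-9))
  expect_error(rbf_kernel(A, B, 0), "configuration error")
  expect_error(rbf_kernel(A, B[, 1:2], 1), "data error")
})

test_that("fit_lssvr solves the dual system like a dense block oracle", {
  set.seed(302)
  X <- matrix(rnorm(20), 10, 2)
  y <- sin(X[, 1]) + 0.3 * X[, 2] + rnorm(10, sd = 0.05)
  gamma <- 50
  sigma2 <- 3
  m <- fit_lssvr(X, y, gamma, sigma2)

  # independent dense solve of [[0, 1'], [1, K + I/gamma]]
  K <- exp(-as.matrix(stats::dist(X))^2 / sigma2)
  C <- rbind(c(0, rep(1, 10)), cbind(1, K + diag(1 / gamma, 10)))
  sol <- unname(solve(C, c(0, y)))
  expect_equal(m$bias, sol[1], tolerance = 1e-8)
  expect_equal(m$alpha, sol[-1], tolerance = 1e-8)

  # KKT residual and the alpha/gamma residual identity
  expect_lt(max(abs(C %*% c(m$bias, m$alpha) - c(0, y))), 1e-8)
  expect_equal(y - predict(m), m$alpha / gamma, tolerance = 1e-8)

  # gamma -> infinity interpolates the training data
  resid_norm <- vapply(c(1, 100, 1e4, 1e8), function(g)
    sqrt(sum((y - predict(fit_lssvr(X, y, g, sigma2)))^2)), numeric(1))
  expect_true(all(diff(resid_norm) < 0))
  expect_lt(resid_norm[4], 1e-4)

  # constant response: bias = constant, alpha ~ 0
  mc <- fit_lssvr(X, rep(2.5, 10), gamma, sigma2)
  expect_equal(mc$bias, 2.5, tolerance = 1e-6)
  expect_lt(max(abs(mc$alpha)), 1e-6)

  expect_error(fit_lssvr(X, y, -1, sigma2), "configuration error")
})

test_that("grid_search_lssvr minimizes exact LOOCV rmse", {
  gen <- generate_synthetic_table(synthetic_spec(18, 5, 2, noise_sd = 0.2, seed = 303))
  subset <- c(1, 2)

  single <- grid_search_lssvr(gen$table, subset, gamma_grid = 10,
                              sigma2_grid = 5)
  expect_equal(single$gamma, 10)
  expect_equal(single$sigma2, 5)

  gs <- grid_search_lssvr(gen$table, subset,
                          gamma_grid = c(1, 10, 100),
                          sigma2_grid = c(0.5, 5, 50))
  expect_true(all(gs$cv_rmse <= gs$grid$cv_rmse + 1e-12))

  # closed-form LOOCV equals the explicit per-fold refit oracle
  X <- gen$table$X[, subset]
  y <- gen$table$y
  for (i in seq_len(nrow(gs$grid))) {
    loo <- lssvr_loo_predictions(X, y, gs$grid$gamma[i], gs$grid$sigma2[i])
    expect_equal(gs$grid$cv_rmse[i], sqrt(mean((y - loo)^2)), tolerance = 1e-8)
  }

  expect_error(grid_search_lssvr(gen$table, subset, numeric(0), 1),
               "configuration error")
})

test_that("tropsha_roy_stats matches the from-formula oracle", {
  # perfect prediction: everything is 1 and every criterion passes
  y <- c(5.1, 5.9, 6.3, 7.2, 7.8, 8.1)
  perfect <- tropsha_roy_stats(y, y, q2_train = 0.9)
  expect_equal(perfect$rp2, 1)
  expect_equal(perfect$r0p2, 1)
  expect_equal(perfect$rm2, 1)
  expect_equal(perfect$k, 1)
  expect_equal(perfect$k_prime, 1)
  expect_true(all(perfect$passes))

  # doubled predictions force k = 0.5 and k' = 2: R7 fails
  doubled <- tropsha_roy_stats(y, 2 * y, q2_train = 0.9)
  expect_equal(doubled$k, 0.5, tolerance = 1e-12)
  expect_equal(doubled$k_prime, 2, tolerance = 1e-12)
  expect_false(doubled$passes[["R7"]])

  # random 11-point pair against independent formula evaluation
  set.seed(304)
  obs <- rnorm(11, mean = 6.5, sd = 1)
  pred <- obs + rnorm(11, sd = 0.4)
  rep <- tropsha_roy_stats(obs, pred, q2_train = 0.7)
  rp2_o <- cor(obs, pred)^2
  k_o <- sum(obs * pred) / sum(pred^2)
  kp_o <- sum(obs * pred) / sum(obs^2)
  r0_o <- 1 - sum((obs - k_o * pred)^2) / sum((obs - mean(obs))^2)
  r0p_o <- 1 - sum((pred - kp_o * obs)^2) / sum((pred - mean(pred))^2)
  expect_equal(rep$rp2, rp2_o, tolerance = 1e-10)
  expect_equal(rep$k, k_o, tolerance = 1e-10)
  expect_equal(rep$k_prime, kp_o, tolerance = 1e-10)
  expect_equal(rep$r0p2, r0_o, tolerance = 1e-10)
  expect_equal(rep$r0p2_prime, r0p_o, tolerance = 1e-10)
  expect_equal(rep$rm2, rp2_o * (1 - sqrt(max(0, rp2_o - r0_o))),
               tolerance = 1e-10)

  # symmetry: swapping observed and predicted swaps the paired statistics
  swapped <- tropsha_roy_stats(pred, obs, q2_train = 0.7)
  expect_equal(swapped$k, rep$k_prime, tolerance = 1e-12)
  expect_equal(swapped$k_prime, rep$k, tolerance = 1e-12)
  expect_equal(swapped$r0p2, rep$r0p2_prime, tolerance = 1e-12)
  expect_equal(swapped$r0p2_prime, rep$r0p2, tolerance = 1e-12)

  # pass flags recompute from the report's own fields
  with(rep, {
    expect_equal(passes[["R4"]], q2 > 0.5)
    expect_equal(passes[["R5"]], rp2 > 0.6)
    expect_equal(passes[["R6"]],
                 deltas[["delta"]] < 0.1 || deltas[["delta_prime"]] < 0.1)
    expect_equal(passes[["R7"]],
                 (k >= 0.85 && k <= 1.15) || (k_prime >= 0.85 && k_prime <= 1.15))
    expect_equal(passes[["R8"]], rm2 > 0.5 && rm2_prime > 0.5)
  })

  expect_error(tropsha_roy_stats(1:2, 1:2, 0.5), "data error")
})

test_that("loocv_q2 is 1 - PRESS/SS", {
  y <- c(1, 2, 3, 4)
  pred <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(loocv_q2(y, pred),
               1 - sum((y - pred)^2) / sum((y - mean(y))^2))
  expect_equal(loocv_q2(y, y), 1)
})

test_that("applicability_domain computes leverages, h*, and outliers", {
  set.seed(305)
  p <- 8
  n <- 44
  Xtr <- matrix(rnorm(n * p), n, p)
  Xte <- matrix(rnorm(11 * p), 11, p)
  rtr <- rnorm(n, sd = 0.4)
  rte <- rnorm(11, sd = 0.4)
  ad <- applicability_domain(Xtr, Xte, rtr, rte)

  expect_equal(ad$h_star, 3 * 8 / 44)         # = 0.5454..., printed 0.54
  expect_equal(floor(ad$h_star * 100) / 100, 0.54)
  expect_equal(sum(ad$leverages_train), p, tolerance = 1e-8)  # hat trace
  expect_true(all(ad$leverages_train > 0 & ad$leverages_train <= 1))

  # a far-out test compound must exceed the leverage threshold
  far <- rbind(Xte, rep(25, p))
  ad2 <- applicability_domain(Xtr, far, rtr, c(rte, 0.1),
                              test_ids = paste0("t", 1:12))
  expect_gt(ad2$leverages_test[12], ad2$h_star)
  expect_true("t12" %in% ad2$outliers)

  # standardized residuals use the training residual scale
  expect_equal(ad$std_residuals_train, rtr / sd(rtr))
  expect_equal(nrow(ad$williams), n + 11)
})
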