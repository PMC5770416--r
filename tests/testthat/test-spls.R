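test_that("dense sPLS component 1 equals the leading singular vectors", {
  set.seed(501)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("m", 1:4)))
  Y <- matrix(rnorm(18), 6, 3, dimnames = list(NULL, paste0("g", 1:3)))
  fit <- spls_fit(X, Y, keepX = 4, keepY = 3, n_comp = 1)
  sv <- svd(crossprod(scale(X), scale(Y)))
  expect_equal(abs(unname(fit$X_loadings[, 1])), abs(sv$u[, 1]),
               tolerance = 1e-8)
  expect_equal(abs(unname(fit$Y_loadings[, 1])), abs(sv$v[, 1]),
               tolerance = 1e-8)
  expect_true(all(fit$converged))
})

test_that("a response equal to one predictor is selected with unit loading", {
  set.seed(502)
  X <- matrix(rnorm(30), 6, 5, dimnames = list(NULL, paste0("m", 1:5)))
  Y <- X[, 3, drop = FALSE]
  colnames(Y) <- "g1"
  fit <- spls_fit(X, Y, keepX = 1, keepY = 1, n_comp = 1)
  w <- fit$X_loadings[, 1]
  expect_equal(sum(w != 0), 1)
  expect_equal(abs(w["m3"]), 1, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("keepY controls the per-component support size exactly", {
  set.seed(503)
  X <- matrix(rnorm(60), 10, 6)
  Y <- matrix(rnorm(80), 10, 8)
  fit <- spls_fit(X, Y, keepX = 6, keepY = 1, n_comp = 2)
  expect_equal(colSums(fit$Y_loadings != 0), c(1, 1), ignore_attr = TRUE)
  fit3 <- spls_fit(X, Y, keepX = 2, keepY = 3, n_comp = 2)
  expect_true(all(colSums(fit3$X_loadings != 0) <= 2))
  expect_true(all(colSums(fit3$Y_loadings != 0) <= 3))
})

test_that("regression-mode deflation makes X-scores orthogonal", {
  set.seed(504)
  X <- matrix(rnorm(120), 12, 10)
  Y <- matrix(rnorm(96), 12, 8)
  fit <- spls_fit(X, Y, n_comp = 3)
  g <- crossprod(fit$X_scores)
  expect_equal(g[upper.tri(g)], rep(0, 3), tolerance = 1e-8)
})

test_that("exhausted cross-covariance truncates the model with a warning", {
  set.seed(505)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("m1", "m2")))
  Y <- X %*% matrix(rnorm(8), 2, 4) +
    matrix(rnorm(24, sd = 1e-4), 6, 4)
  colnames(Y) <- paste0("g", 1:4)
  expect_warning(fit <- spls_fit(X, Y, n_comp = 4), "truncat")
  expect_lte(fit$n_comp, 2)
  expect_equal(ncol(fit$X_loadings), fit$n_comp)
  expect_equal(length(fit$converged), fit$n_comp)
})

test_that("degenerate inputs raise errors", {
  X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("m1", "m2")))
  Y <- matrix(rnorm(6), 6, 1, dimnames = list(NULL, "g1"))
  Xz <- X; Xz[, 2] <- 5
  expect_error(spls_fit(Xz, Y), "zero-variance.*m2")
  expect_error(spls_fit(X, Y[1:5, , drop = FALSE]), "observation rows")
  expect_error(spls_fit(X, Y, keepX = 0), "keepX/keepY")
})

test_that("prediction reproduces the training fit on the training data", {
  set.seed(506)
  X <- matrix(rnorm(60), 10, 6)
  Y <- X %*% matrix(rnorm(24), 6, 4) + matrix(rnorm(40, sd = 0.1), 10, 4)
  colnames(Y) <- paste0("g", 1:4)
  fit <- spls_fit(X, Y, n_comp = 4)
  pred <- predict_spls(fit, X)
  expect_equal(pred$scores, fit$X_scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  ysc <- scale(Y)
  # covariance components approximate (not equal) the least-squares fit, so
  # require a small residual that shrinks as components are added
  expect_lt(mean((pred$Y_scaled - ysc)^2), 0.15)
  fit1 <- spls_fit(X, Y, n_comp = 1)
  pred1 <- predict_spls(fit1, X)
  expect_lt(mean((pred$Y_scaled - ysc)^2),
            mean((pred1$Y_scaled - scale(Y))^2))
})

test_that("tuning returns the singleton grid value and reports the grid MSE", {
  set.seed(507)
  X <- matrix(rnorm(40), 8, 5)
  Y <- matrix(rnorm(48), 8, 6)
  res <- tune_spls_keepy(X, Y, keepY_grid = 4, n_comp = 1)
  expect_equal(res$keepY, 4)
  expect_named(res$loo_mse, "4")
  expect_error(tune_spls_keepy(X, Y, keepY_grid = integer(0)), "non-empty")
})

test_that("tuning prefers the sparsity matching the true support", {
  set.seed(508)
  n <- 14
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("m1", "m2")))
  noise <- matrix(rnorm(n * 6), n, 6)
  Y <- cbind(-3 * X[, 1] + rnorm(n, sd = 0.1),
             3 * X[, 2] + rnorm(n, sd = 0.1), noise)
  colnames(Y) <- paste0("g", 1:8)
  res <- tune_spls_keepy(X, Y, keepY_grid = c(2, 8), n_comp = 2)
  expect_equal(res$keepY, 2)
  expect_lt(res$loo_mse["2"], res$loo_mse["8"])
})

test_that("tied leave-one-out error resolves to the smallest keepY", {
  set.seed(509)
  X <- matrix(rnorm(24), 8, 3)
  Y <- matrix(rnorm(16), 8, 2)
  # every grid value clamps to ncol(Y) = 2, so errors tie exactly
  res <- tune_spls_keepy(X, Y, keepY_grid = c(5, 9), n_comp = 1)
  expect_equal(res$keepY, 2)
})
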