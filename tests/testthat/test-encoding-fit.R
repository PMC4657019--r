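test_that("voxel selection ranks by t, applies the cap and strict threshold", {
  set.seed(41L)
  # all-zero responses: nothing selected
  expect_equal(select_voxels(matrix(0, 10L, 5L))$n_selected, 0L)

  # 6000 strongly responsive voxels: exactly the cap of 5000 survives
  S <- 20L
  Y <- matrix(1, S, 6000L) + matrix(stats::rnorm(S * 6000L, sd = 0.01), S)
  sel <- select_voxels(Y, t_threshold = 2.9, cap = 5000L)
  expect_equal(sel$n_selected, 5000L)
  expect_true(all(diff(sel$t_values) <= 0))      # ranked by t
  expect_true(all(sel$t_values > 2.9))

  # a voxel sitting exactly at the threshold is excluded (strict >)
  y1 <- c(1, 2, 3, 4, 5, 6)
  t1 <- mean(y1) / (stats::sd(y1) / sqrt(6))
  expect_equal(select_voxels(matrix(y1), t_threshold = t1)$n_selected, 0L)
  expect_equal(select_voxels(matrix(y1), t_threshold = t1 - 1e-9)$n_selected, 1L)

  expect_error(select_voxels(Y, mask = logical(6000L)), "empty")
})

test_that("eigendecomposition ridge matches the explicit solve on the grid", {
  ds <- make_small_dataset(n_train = 56L, n_test = 28L, n_voxels = 20L,
                           seed = 8L)
  fw <- train_test_features(ds, "joint")
  Y <- ds$Y[fw$train, ]
  grid <- default_lambda_grid(fw$W_train)
  expect_length(grid, 25L)
  Wc <- scale(unclass(fw$W_train), center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  for (lam in grid) {
    fit <- ridge_solve(fw$W_train, Y, lambda_fixed = rep(lam, ncol(Y)))
    oracle <- solve(crossprod(Wc) + lam * diag(42L), crossprod(Wc, Yc))
    expect_lt(max(abs(fit$weights - oracle)) / max(abs(oracle)), 1e-8)
  }
})

test_that("lambda -> 0 reduces to ordinary least squares on full rank data", {
  set.seed(42L)
  W <- matrix(stats::rnorm(20 * 5), 20L, 5L)
  y <- matrix(stats::rnorm(20), 20L, 1L)
  fit <- ridge_solve(W, y, lambda_fixed = 0)
  Wc <- scale(W, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  ols <- solve(crossprod(Wc), crossprod(Wc, yc))
  expect_equal(fit$weights, ols, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("noise-free weights are recovered as lambda -> 0", {
  ds <- make_small_dataset(n_train = 56L, n_test = 28L, n_voxels = 10L,
                           noise_sd = 0, seed = 9L)
  fw <- train_test_features(ds, "joint")
  fit <- ridge_solve(fw$W_train, ds$Y[fw$train, ],
                     lambda_fixed = rep(1e-9, 10L))
  expect_equal(fit$weights, ds$R_true, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("the ridge trace shrinks monotonically along the grid", {
  ds <- make_small_dataset(n_train = 28L, n_test = 14L, n_voxels = 8L,
                           seed = 10L)
  fw <- train_test_features(ds, "joint")
  Y <- ds$Y[fw$train, ]
  grid <- default_lambda_grid(fw$W_train)
  norms <- vapply(grid, function(lam) {
    f <- ridge_solve(fw$W_train, Y, lambda_fixed = rep(lam, ncol(Y)))
    sqrt(colSums(f$weights^2))
  }, numeric(ncol(Y)))
  expect_true(all(diff(t(norms)) <= 1e-12))
})

test_that("fitting commutes with voxel permutation and is linear in Y", {
  ds <- make_small_dataset(n_train = 28L, n_test = 14L, n_voxels = 12L,
                           seed = 11L)
  fw <- train_test_features(ds, "joint")
  Y <- ds$Y[fw$train, ]
  fit <- ridge_solve(fw$W_train, Y)
  perm <- sample(ncol(Y))
  fit_p <- ridge_solve(fw$W_train, Y[, perm])
  expect_equal(fit_p$weights, fit$weights[, perm])
  expect_equal(fit_p$lambdas, fit$lambdas[perm])

  lam <- rep(fit$lambda_grid[10L], ncol(Y))
  f1 <- ridge_solve(fw$W_train, Y, lambda_fixed = lam)
  f2 <- ridge_solve(fw$W_train, 2 * Y, lambda_fixed = lam)
  f3 <- ridge_solve(fw$W_train, Y + 2 * Y, lambda_fixed = lam)
  expect_equal(f3$weights, f1$weights + f2$weights, tolerance = 1e-10)
})

test_that("prediction restores means, respects labels and linearity", {
  ds <- make_small_dataset(n_train = 28L, n_test = 14L, n_voxels = 6L,
                           noise_sd = 0, seed = 12L)
  fw <- train_test_features(ds, "joint")
  Y <- ds$Y[fw$train, ]
  fit <- ridge_solve(fw$W_train, Y, lambda_fixed = rep(1e-9, 6L))
  # training prediction reproduces the noise-free training data
  expect_equal(predict(fit, fw$W_train), Y, tolerance = 1e-6,
               ignore_attr = TRUE)
  # zero weights predict zero for zero-mean responses
  fit0 <- fit
  fit0$weights[] <- 0
  fit0$y_means[] <- 0
  expect_true(all(predict(fit0, fw$W_test) == 0))
  # feature labels are load-bearing
  W_bad <- fw$W_test
  colnames(W_bad) <- rev(colnames(W_bad))
  expect_error(predict(fit, W_bad), "labels")
  expect_error(ridge_solve(fw$W_train, Y * NA), "non-finite")
})
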