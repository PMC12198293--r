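test_that("the lag matrix has n_features x (lags + 1) columns", {
  set.seed(31)
  s <- matrix(rbinom(400, 1, 0.05), 200, 2)
  X <- build_lag_matrix(s, 0, 0.7, fs_env = 100)
  expect_equal(ncol(X), 2 * 71)
  expect_equal(nrow(X), 200)
  # row t of the lag-l column holds the stimulus at t - l
  for (l in c(0, 3, 70))
    expect_equal(X[(l + 1):200, l + 1], s[1:(200 - l), 1])
  # zero-padding before the trial start
  expect_true(all(X[1:5, 6] == 0) || s[1, 1] == 0)
})

test_that("a single zero lag reproduces the stimulus", {
  set.seed(32)
  s <- rbinom(50, 1, 0.2)
  X <- build_lag_matrix(s, 0, 0.5 / 100, fs_env = 100)
  expect_equal(X[, 1], s)
  expect_error(build_lag_matrix(s, 0, 2, fs_env = 100), "trial length")
  expect_error(build_lag_matrix(s, 0.5, 0.2, fs_env = 100), "lag")
})

test_that("ridge with lambda = 0 on an orthonormal design equals X'y", {
  set.seed(33)
  Q <- qr.Q(qr(matrix(rnorm(200 * 5), 200, 5)))
  Q <- sweep(Q, 2, colMeans(Q))            # center, then re-orthonormalize
  Q <- qr.Q(qr(Q))
  y <- rnorm(200)
  m <- fit_ridge(Q, y, 0)
  expect_equal(m$weights, drop(crossprod(Q, y - mean(y))),
               tolerance = 1e-10)
})

test_that("a tiny system matches the hand normal-equations solve", {
  X <- cbind(c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 1))
  y <- c(1.2, 1.9, 3.1, 4.2, 4.8)
  lam <- 0.5
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  w_hand <- solve(crossprod(Xc) + lam * diag(2), crossprod(Xc, yc))
  m <- fit_ridge(X, y, lam)
  expect_equal(m$weights, drop(w_hand), tolerance = 1e-12)
  expect_equal(m$intercept, mean(y) - sum(colMeans(X) * m$weights),
               tolerance = 1e-12)
})

test_that("ridge weights shrink monotonically to zero as lambda grows", {
  set.seed(34)
  X <- matrix(rnorm(100 * 6), 100, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(100)
  norms <- vapply(10^seq(-2, 6, by = 1), function(l)
    sqrt(sum(fit_ridge(X, y, l)$weights^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-3)
})

test_that("a rank-deficient design with lambda = 0 advises regularization", {
  X <- cbind(1:10, 2 * (1:10))
  expect_error(fit_ridge(X, rnorm(10), 0), "ridge_lambda")
})

test_that("fit_ridge matches the augmented-least-squares oracle", {
  set.seed(35)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    p <- sample(2:20, 1)
    lam <- 10^runif(1, -3, 2)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- fit_ridge(X, y, lam)
    o <- ridge_oracle(X, y, lam)
    expect_lt(max(abs(m$weights - o$weights)) /
                max(abs(o$weights)), 1e-8)
  }
})

test_that("prediction is the onset-shifted kernel, and is linear", {
  fs <- 100
  kern <- exp(-((0:70) / fs - 0.2)^2 / (2 * 0.04^2))
  sA <- numeric(200); sA[30] <- 1
  sB <- numeric(200); sB[120] <- 1
  m <- structure(list(weights = kern, intercept = 0.5, ridge_lambda = 0),
                 class = "trf_model")
  XA <- build_lag_matrix(sA, 0, 0.7, fs)
  pA <- predict(m, XA)
  expect_equal(pA[30:100], kern + 0.5, tolerance = 1e-12)
  XB <- build_lag_matrix(sB, 0, 0.7, fs)
  XAB <- build_lag_matrix(sA + sB, 0, 0.7, fs)
  expect_equal(predict(m, XAB),
               predict(m, XA) + predict(m, XB) - m$intercept,
               tolerance = 1e-12)
})

test_that("predict(fit(X, y, 0), X) reproduces the oracle fitted values", {
  set.seed(36)
  X <- matrix(rnorm(80 * 4), 80, 4)
  y <- rnorm(80)
  m <- fit_ridge(X, y, 0)
  o <- ridge_oracle(X, y, 0)
  expect_equal(predict(m, X),
               drop(sweep(X, 2, colMeans(X)) %*% o$weights) + mean(y),
               tolerance = 1e-9)
})

test_that("cross-validation on a noiseless session is near-perfect", {
  s <- make_test_session(n_trials = 15, fs = 200, noise_sd = 0, seed = 44)
  inp <- prep_trf_inputs(s, fs_env = 50)
  cv <- crossval_corr(inp$stim, inp$env_list, fs_env = 50, seed = 1)
  expect_equal(length(cv$fold_r), 5)
  expect_equal(cv$mean_r, mean(cv$fold_r))
  expect_gt(cv$mean_r, 0.99)
})

test_that("estimated kernels match the generating kernels when noiseless", {
  s <- make_test_session(n_trials = 15, fs = 200, noise_sd = 0, seed = 45)
  inp <- prep_trf_inputs(s, fs_env = 50)
  m <- fit_trf(inp$stim, inp$env_list, fs_env = 50)
  expect_gt(cor(m$weights[1, ], kernel_weights(default_kernels()$attended,
                                               50)), 0.95)
  expect_gt(cor(m$weights[2, ], kernel_weights(default_kernels()$unattended,
                                               50)), 0.95)
})

test_that("kernel recovery degrades monotonically with noise", {
  rec <- vapply(c(0, 0.3, 1.5), function(ns) {
    s <- make_test_session(n_trials = 15, fs = 200, noise_sd = ns,
                           seed = 46)
    inp <- prep_trf_inputs(s, fs_env = 50)
    m <- fit_trf(inp$stim, inp$env_list, fs_env = 50)
    cor(m$weights[1, ], kernel_weights(default_kernels()$attended, 50))
  }, numeric(1))
  expect_true(all(diff(rec) < 0))
  expect_gt(rec[1], 0.95)
})

test_that("cross-validated r is near zero for an unrelated response", {
  s <- make_test_session(n_trials = 10, fs = 200, noise_sd = 0, seed = 47)
  inp <- prep_trf_inputs(s, fs_env = 50)
  set.seed(48)
  rs <- vapply(1:100, function(i) {
    noise <- lapply(inp$env_list, function(y) rnorm(length(y)))
    crossval_corr(inp$stim, noise, fs_env = 50)$mean_r
  }, numeric(1))
  n_samples <- sum(lengths(inp$env_list))
  expect_lt(abs(mean(rs)), 3 / sqrt(n_samples))
})

test_that("fold assignment is seeded and reproducible", {
  s <- make_test_session(n_trials = 12, fs = 200, noise_sd = 0.4, seed = 49)
  inp <- prep_trf_inputs(s, fs_env = 50)
  cv1 <- crossval_corr(inp$stim, inp$env_list, fs_env = 50, seed = 5)
  cv2 <- crossval_corr(inp$stim, inp$env_list, fs_env = 50, seed = 5)
  expect_identical(cv1$mean_r, cv2$mean_r)
  expect_identical(cv1$folds, cv2$folds)
  expect_error(crossval_corr(inp$stim[1:3], inp$env_list[1:3], fs_env = 50),
               "fewer trials")
})
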