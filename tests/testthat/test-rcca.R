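test_that("identity and scalar reductions give exact canonical correlations", {
  set.seed(1)
  X <- matrix(rnorm(30 * 3), 30)
  expect_equal(fit_rcca(X, X)$canonical_corr, 1, tolerance = 1e-9)
  x <- rnorm(25); y <- 0.6 * x + rnorm(25)
  expect_equal(fit_rcca(cbind(x), cbind(y))$canonical_corr, abs(cor(x, y)),
               tolerance = 1e-9)
})

test_that("unregularized fit matches the classical CCA solution", {
  set.seed(2)
  n <- 20
  X <- matrix(rnorm(n * 2), n); Y <- matrix(rnorm(n * 3), n)
  f <- fit_rcca(X, Y)
  cc <- cancor(scale(X), scale(Y))
  expect_equal(f$canonical_corr, cc$cor[1], tolerance = 1e-9)
  ## weights span the same direction up to sign/scale
  expect_equal(abs(cor(as.vector(scale(X) %*% cc$xcoef[, 1]), f$U)), 1,
               tolerance = 1e-9)
})

test_that("canonical correlation is invariant to affine rescaling of columns", {
  set.seed(3)
  X <- matrix(rnorm(25 * 3), 25); Y <- matrix(rnorm(25 * 4), 25)
  f1 <- fit_rcca(X, Y, 0.1, 0.1)
  X2 <- X; X2[, 2] <- -7 * X2[, 2] + 3
  Y2 <- Y; Y2[, 1] <- 0.01 * Y2[, 1] - 5
  f2 <- fit_rcca(X2, Y2, 0.1, 0.1)
  expect_equal(f1$canonical_corr, f2$canonical_corr, tolerance = 1e-9)
})

test_that("singular covariance without regularization is an instructive error", {
  set.seed(4)
  X <- matrix(rnorm(10 * 2), 10); Y <- matrix(rnorm(10 * 15), 10)
  expect_error(fit_rcca(X, Y, 0, 0), "lambda_y > 0")
  expect_silent(fit_rcca(X, Y, 0, 0.5))
})

test_that("regularized fit agrees with an independent rCCA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(5)
  n <- 30
  X <- matrix(rnorm(n * 4), n); Y <- matrix(rnorm(n * 6), n)
  Y[, 1] <- Y[, 1] + X[, 1]
  f <- fit_rcca(X, Y, 0.2, 0.3)
  ref <- mixOmics::rcc(scale(X), scale(Y), method = "ridge",
                       lambda1 = 0.2, lambda2 = 0.3)
  ## same first canonical pair: variates collinear, same empirical correlation
  expect_gt(abs(cor(ref$variates$X[, 1], f$U)), 0.98)
  expect_gt(abs(cor(ref$variates$Y[, 1], f$V)), 0.98)
  expect_equal(unname(abs(cor(ref$variates$X[, 1], ref$variates$Y[, 1]))),
               f$canonical_corr, tolerance = 0.02)
})

test_that("grid search recovers a planted latent factor at q >> n", {
  set.seed(6)
  n <- 40; q <- 500
  z <- rnorm(n)
  X <- cbind(z + rnorm(n, 0, 0.5), rnorm(n), rnorm(n))
  Y <- matrix(rnorm(n * q), n); Y[, 1:50] <- Y[, 1:50] + z
  gs <- grid_search_lambdas(X, Y, k_folds = 5, seed = 2)
  expect_gt(gs$cv_corr, 0.5)
  ## degenerate single-pair grid returns that pair unchanged
  g1 <- grid_search_lambdas(X, Y, grid = data.frame(lambda_x = 0.5, lambda_y = 2))
  expect_equal(g1$lambda$lambda_x, 0.5)
  expect_equal(g1$fit$lambda_y, 2)
  expect_error(grid_search_lambdas(X[1:8, ], Y[1:8, ], k_folds = 5), "folds")
})

test_that("pure-noise pairs give near-zero cross-validated correlation", {
  set.seed(7)
  cvs <- replicate(10, {
    X <- matrix(rnorm(30 * 3), 30); Y <- matrix(rnorm(30 * 40), 30)
    grid_search_lambdas(X, Y, grid = expand.grid(lambda_x = c(0.1, 1),
                                                 lambda_y = c(1, 10)),
                        k_folds = 5, seed = 1)$cv_corr
  })
  expect_lt(abs(mean(cvs)), 0.15)
})

test_that("permutation CIs flag a planted driver and stay quiet otherwise", {
  set.seed(8)
  n <- 40; q <- 60
  z <- rnorm(n)
  X <- cbind(driver = z + rnorm(n, 0, 0.4), a = rnorm(n), b = rnorm(n))
  Y <- matrix(rnorm(n * q), n) - z    # negative association with the driver
  fit <- fit_rcca(X, Y, 0.1, 1)
  fit <- permutation_loading_cis(fit, X, Y, n_perm = 300, seed = 4)
  expect_true(fit$ci99$x$significant[1])
  ## negative brain-behavior association: driver and Y loadings oppose
  expect_lt(fit$ci99$x$loading[1] * mean(fit$ci99$y$loading), 0)
  ## no-op permutation count keeps point estimates and adds no CIs
  f0 <- permutation_loading_cis(fit_rcca(X, Y, 0.1, 1), X, Y, n_perm = 0)
  expect_null(f0$ci99)
  expect_warning(permutation_loading_cis(fit_rcca(X, Y, 0.1, 1), X, Y, n_perm = 50,
                                         seed = 1),
                 "100")
})

test_that("fits and CIs are reproducible under a fixed seed", {
  set.seed(9)
  X <- matrix(rnorm(30 * 3), 30); Y <- matrix(rnorm(30 * 20), 30)
  f1 <- permutation_loading_cis(fit_rcca(X, Y, 0.5, 0.5), X, Y, n_perm = 120, seed = 5)
  f2 <- permutation_loading_cis(fit_rcca(X, Y, 0.5, 0.5), X, Y, n_perm = 120, seed = 5)
  expect_identical(f1$ci99$x, f2$ci99$x)
  expect_identical(f1$u_weights, f2$u_weights)
})
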