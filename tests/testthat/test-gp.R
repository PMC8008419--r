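test_that("squared-exponential kernel matches direct substitution and is symmetric", {
  expect_equal(se_kernel(c(1, 2), c(1, 2), 0.7, c(1, 1)), 0.7)
  expect_equal(se_kernel(0, 1, 1, 1), exp(-1))
  set.seed(4)
  for (i in 1:100) {
    x <- runif(3); y <- runif(3); ls <- runif(3, 0.1, 2); s <- runif(1, 0.1, 2)
    expect_identical(se_kernel(x, y, s, ls), se_kernel(y, x, s, ls))
  }
  expect_error(se_kernel(1:2, 1:3, 1, 1), "dimension mismatch")
})

test_that("log marginal likelihood matches closed form and dense algebra", {
  # single observation, centred target zero
  expect_equal(
    log_marginal_likelihood(matrix(0.3), 0, noise_var = 0.01, sigma = 0.5,
                            lengthscales = 1, offset = 0),
    -0.5 * log(0.51) - 0.5 * log(2 * pi))
  set.seed(11)
  for (i in 1:5) {
    n <- sample(3:5, 1)
    X <- matrix(runif(2 * n), n, 2)
    y <- rnorm(n)
    nv <- runif(n, 1e-4, 1e-2)
    s <- runif(1, 0.05, 1); ls <- runif(2, 0.1, 3)
    expect_equal(log_marginal_likelihood(X, y, nv, s, ls),
                 oracle_gp_lml(X, y, nv, s, ls), tolerance = 1e-8)
  }
})

test_that("duplicated training points do not break the factorisation", {
  X <- rbind(c(0.2, 0.2), c(0.8, 0.5), c(0.2, 0.2))
  y <- c(0.1, 0.3, 0.1)
  ll <- log_marginal_likelihood(X, y, rep(1e-6, 3), sigma = 0.5, lengthscales = c(1, 1))
  expect_true(is.finite(ll))
})

test_that("predictive moments match explicit two-point matrix algebra", {
  X <- rbind(c(0.1, 0.9), c(0.7, 0.3))
  y <- c(0.2, 0.5)
  nv <- c(0.004, 0.001)
  m <- fit_gp(X, y, nv, space = unit_space_2d(),
              control = gp_control(n_starts = 2, maxit = 10))
  xs <- c(0.4, 0.5)
  pr <- predict(m, matrix(xs, 1))
  or <- oracle_gp_predict(ssdopt:::space_scale(m$space, X), y, nv, m$sigma,
                          m$lengthscales, xs, offset = m$offset)
  expect_equal(pr$mean, or$mean, tolerance = 1e-10)
  expect_equal(pr$var, or$var, tolerance = 1e-10)
})

test_that("noiseless observations are interpolated; far points revert to the prior", {
  set.seed(2)
  X <- sobol_sequence(15, 2, seed = 9)
  y <- sin(3 * X[, 1]) + X[, 2]
  m <- fit_gp(X, y, rep(1e-10, 15), space = unit_space_2d())
  pr <- predict(m, X)
  expect_lt(max(abs(pr$mean - y)), 1e-3)
  far <- predict(m, matrix(c(80, -40), 1))
  expect_equal(far$mean, m$offset)
  expect_equal(far$var, m$sigma)
})

test_that("constant targets predict that constant everywhere", {
  X <- sobol_sequence(10, 2, seed = 1)
  m <- fit_gp(X, rep(0.42, 10), rep(1e-6, 10), space = unit_space_2d())
  pr <- predict(m, matrix(runif(10), 5, 2))
  expect_lt(max(abs(pr$mean - 0.42)), 1e-6)
})

test_that("fits are invariant to training-order permutation", {
  set.seed(8)
  X <- sobol_sequence(12, 2, seed = 3)
  y <- X[, 1]^2 + rnorm(12, 0, 0.01)
  nv <- rep(1e-4, 12)
  perm <- sample(12)
  m1 <- fit_gp(X, y, nv, space = unit_space_2d())
  m2 <- fit_gp(X[perm, ], y[perm], nv[perm], space = unit_space_2d())
  grid <- matrix(runif(20), 10, 2)
  expect_lt(max(abs(predict(m1, grid)$mean - predict(m2, grid)$mean)), 1e-8)
  expect_lt(max(abs(predict(m1, grid)$var - predict(m2, grid)$var)), 1e-8)
})

test_that("length-scales are recovered within a factor of two on simulated draws", {
  set.seed(31)
  n <- 40
  X <- sobol_sequence(n, 1, seed = 13)
  true_ls <- 0.3
  K <- outer(X[, 1], X[, 1], function(a, b) exp(-(a - b)^2 / true_ls^2))
  y <- drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n))  # sigma = 1 draw
  y <- y - mean(y)
  m <- fit_gp(X, y, rep(1e-6, n),
              space = solution_space("x", 0, 1))
  expect_gt(m$lengthscales, true_ls / 2)
  expect_lt(m$lengthscales, true_ls * 2)
})

test_that("observing a location never increases its predictive variance", {
  set.seed(5)
  X <- sobol_sequence(10, 2, seed = 21)
  y <- X[, 1] + 0.5 * X[, 2]
  nv <- rep(0.005, 10)
  xnew <- c(0.55, 0.35)
  m1 <- fit_gp(X, y, nv, space = unit_space_2d())
  v_before <- predict(m1, matrix(xnew, 1))$var
  # same hyperparameters, augmented data: isolate the information effect
  m2 <- m1
  X2 <- rbind(X, xnew)
  y2 <- c(y, 0.7)
  sq <- ssdopt:::.sqdist_list(ssdopt:::space_scale(m1$space, X2))
  K <- ssdopt:::.kernel_from_sqdist(sq, m1$sigma, m1$lengthscales)
  cj <- ssdopt:::.chol_with_jitter(K, c(nv, 0.005))
  m2$X <- X2; m2$Xs <- ssdopt:::space_scale(m1$space, X2)
  m2$y <- y2; m2$noise_var <- c(nv, 0.005); m2$chol <- cj$chol
  m2$alpha <- drop(backsolve(cj$chol, backsolve(cj$chol, y2 - m2$offset, transpose = TRUE)))
  v_after <- predict(m2, matrix(xnew, 1))$var
  expect_lte(v_after, v_before + 1e-12)
})

test_that("the surrogate beats a constant predictor on the analytic power surface", {
  params <- cluster_params()
  space <- solution_space(c("k", "n"), c(10, 100), c(100, 500), c(TRUE, TRUE))
  X <- sobol_design(space, 50, seed = 17)
  y <- cluster_power_analytic(X[, "k"], X[, "n"], params)
  m <- fit_gp(X, y, rep(1e-8, 50), space = space)
  grid <- sobol_design(space, 200, seed = 18)
  truth <- cluster_power_analytic(grid[, "k"], grid[, "n"], params)
  rmse_gp <- sqrt(mean((predict(m, grid)$mean - truth)^2))
  rmse_const <- sqrt(mean((mean(y) - truth)^2))
  expect_lt(rmse_gp * 5, rmse_const)
})
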