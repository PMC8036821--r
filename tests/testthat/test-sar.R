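test_that("spatial fits at zero autocorrelation agree with OLS", {
  W <- lattice_weights(10, 10)
  set.seed(41)
  dgp <- make_dgp(W, k = 3, par = 0, process = "none")
  rhos <- lambdas <- numeric(30)
  for (b in 1:30) {
    y <- dgp$draw()
    rhos[b] <- fit_spatial_lag(dgp$X, y, W, compute_se = FALSE)$rho
    lambdas[b] <- fit_spatial_error(dgp$X, y, W, compute_se = FALSE)$lambda
  }
  expect_lt(abs(mean(rhos)), 0.05)
  expect_lt(abs(mean(lambdas)), 0.08)
  # on one draw, beta agrees with OLS within 2 OLS standard errors
  y <- dgp$draw()
  ols <- fit_ols(dgp$X, y)
  lag <- fit_spatial_lag(dgp$X, y, W, compute_se = FALSE)
  err <- fit_spatial_error(dgp$X, y, W, compute_se = FALSE)
  expect_true(all(abs(lag$coefficients - ols$coefficients) < 2 * ols$se))
  expect_true(all(abs(err$coefficients - ols$coefficients) < 2 * ols$se))
  # the concentrated log-likelihood at 0 equals the Gaussian OLS loglik
  expect_equal(concentrated_loglik(dgp$X, y, W, "lag", at = 0), ols$loglik,
               tolerance = 1e-10)
  expect_equal(concentrated_loglik(dgp$X, y, W, "error", at = 0), ols$loglik,
               tolerance = 1e-10)
})

test_that("concentrated likelihood matches a dense log-determinant path", {
  # direct evaluation: profile beta/sigma by hand with a dense determinant
  for (dims in list(c(4, 4), c(8, 8))) {
    W <- lattice_weights(dims[1], dims[2])
    n <- W$n
    Wm <- weights_matrix(W)
    set.seed(50 + n)
    dgp <- make_dgp(W, k = 2, par = 0.5, process = "lag")
    y <- dgp$draw()
    X1 <- cbind(1, dgp$X)
    rhos <- seq(-0.85, 0.85, by = 0.17)
    ours <- concentrated_loglik(dgp$X, y, W, "lag", at = rhos)
    direct <- vapply(rhos, function(rho) {
      ys <- y - rho * drop(Wm %*% y)
      e <- ys - drop(X1 %*% solve(t(X1) %*% X1, t(X1) %*% ys))
      ld <- as.numeric(determinant(diag(n) - rho * Wm, TRUE)$modulus)
      -n / 2 * (log(2 * pi) + 1) - n / 2 * log(sum(e^2) / n) + ld
    }, numeric(1))
    expect_equal(ours, direct, tolerance = 1e-8)
  }
})

test_that("optimizer matches a brute-force grid search", {
  W <- lattice_weights(10, 10)
  grid <- seq(-0.989, 0.989, by = 0.001)
  set.seed(60)
  for (i in 1:5) {
    par <- runif(1, -0.3, 0.7)
    dgp <- make_dgp(W, k = 3, par = par, process = "lag")
    y <- dgp$draw()
    fit <- fit_spatial_lag(dgp$X, y, W, compute_se = FALSE)
    prof <- concentrated_loglik(dgp$X, y, W, "lag", at = grid)
    expect_lt(abs(fit$rho - grid[which.max(prof)]), 0.002)

    dgp2 <- make_dgp(W, k = 3, par = par, process = "error")
    y2 <- dgp2$draw()
    fit2 <- fit_spatial_error(dgp2$X, y2, W, compute_se = FALSE)
    prof2 <- concentrated_loglik(dgp2$X, y2, W, "error", at = grid)
    expect_lt(abs(fit2$lambda - grid[which.max(prof2)]), 0.002)
  }
})

test_that("standardized coefficients match a refit on z-scored data", {
  set.seed(70)
  X <- matrix(rnorm(150 * 4), 150, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  y <- drop(cbind(1, X) %*% c(2, 1, -1, 0.5, 0)) + rnorm(150)
  f <- fit_ols(X, y)
  fz <- fit_ols(scale(X), drop(scale(y)))
  expect_equal(unname(f$std_beta[-1]), unname(fz$coefficients[-1]),
               tolerance = 1e-10)
  expect_true(is.na(f$std_beta["Constant"]))
  # doubling a column's units leaves the standardized coefficient unchanged
  X2 <- X; X2[, 1] <- 2 * X2[, 1]
  f2 <- fit_ols(X2, y)
  expect_equal(f2$std_beta[-1], f$std_beta[-1], tolerance = 1e-10)
})

test_that("information criteria follow the documented convention", {
  W <- lattice_weights(8, 8)
  set.seed(80)
  dgp <- make_dgp(W, k = 3, par = 0.5, process = "lag")
  y <- dgp$draw()
  ols <- fit_ols(dgp$X, y)
  lag <- fit_spatial_lag(dgp$X, y, W)
  # K = #beta + 1 (sigma^2), +1 spatial parameter for the lag model
  expect_equal(ols$aic, 2 * (ols$k + 1) - 2 * ols$loglik)
  expect_equal(lag$aic, 2 * (lag$k + 2) - 2 * lag$loglik)
  expect_equal(information_criteria(lag)$aic, lag$aic)
  expect_equal(attr(logLik(lag), "df"), lag$k + 2)
  # the larger (lag) model cannot have smaller maximized likelihood
  expect_gte(lag$loglik, ols$loglik - 1e-8)
})

test_that("estimates are invariant to tract reordering", {
  W <- lattice_weights(6, 6)
  set.seed(90)
  dgp <- make_dgp(W, k = 2, par = 0.4, process = "lag")
  y <- dgp$draw()
  f <- fit_spatial_lag(dgp$X, y, W, compute_se = FALSE)
  perm <- sample(36)
  Wp <- subset_weights(W, perm)
  fp <- fit_spatial_lag(dgp$X[perm, ], y[perm], Wp, compute_se = FALSE)
  expect_equal(fp$rho, f$rho, tolerance = 1e-6)
  expect_equal(fp$coefficients, f$coefficients, tolerance = 1e-6)
})

test_that("the true model wins pseudo-R2 under strong autocorrelation", {
  W <- lattice_weights(12, 12)
  set.seed(100)
  dgp <- make_dgp(W, k = 2, par = 0.7, process = "lag", sigma = 2)
  wins <- 0L
  for (b in 1:20) {
    y <- dgp$draw()
    lag <- fit_spatial_lag(dgp$X, y, W, compute_se = FALSE)
    ols <- fit_ols(dgp$X, y)
    if (lag$pseudo_r2 > ols$pseudo_r2) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("optima at the interval boundary are flagged as non-converged", {
  # a monotone profile has its maximum at the boundary by construction
  expect_warning(greensar:::sar_optimize(function(r) r, lo = -1.5, hi = 1),
                 "boundary")
  out <- suppressWarnings(
    greensar:::sar_optimize(function(r) r, lo = -1.5, hi = 1)
  )
  expect_false(out$converged)
  interior <- greensar:::sar_optimize(function(r) -(r - 0.3)^2,
                                      lo = -1.5, hi = 1)
  expect_true(interior$converged)
  expect_equal(interior$par, 0.3, tolerance = 1e-6)
})

test_that("Hessian standard errors are finite and well-scaled", {
  W <- lattice_weights(10, 10)
  set.seed(120)
  dgp <- make_dgp(W, k = 2, par = 0.5, process = "lag")
  y <- dgp$draw()
  f <- fit_spatial_lag(dgp$X, y, W)
  expect_true(all(is.finite(f$se)))
  expect_true(is.finite(f$rho_se) && f$rho_se > 0 && f$rho_se < 0.5)
  # true parameters inside +-3 SE most of the time for this seed
  expect_lt(abs(f$rho - 0.5), 3 * f$rho_se)
  fe <- fit_spatial_error(dgp$X, dgp$draw(), W)
  expect_true(all(is.finite(fe$se)))
})
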