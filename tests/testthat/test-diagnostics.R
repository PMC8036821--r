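test_that("OLS recovers exact coefficients and matches normal equations", {
  set.seed(14)
  X <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  beta <- c(3, 1, -2, 0.5, 0, 4)
  # noiseless data: exact recovery
  y0 <- drop(cbind(1, X) %*% beta)
  f0 <- fit_ols(X, y0)
  expect_equal(unname(f0$coefficients), beta, tolerance = 1e-10)
  # noisy data: agreement with the explicit (X'X)^-1 X'y oracle
  y <- y0 + rnorm(200)
  f <- fit_ols(X, y)
  X1 <- cbind(1, X)
  oracle <- unname(drop(solve(t(X1) %*% X1, t(X1) %*% y)))
  expect_equal(unname(f$coefficients), oracle, tolerance = 1e-10)
  # residuals orthogonal to every design column
  expect_lt(max(abs(t(X1) %*% f$residuals)), 1e-8)
})

test_that("outcome orthogonal to centered predictors gives zero slopes", {
  X <- cbind(a = c(-1, 1, -1, 1), b = c(-1, -1, 1, 1))
  y <- rep(5, 4)
  f <- fit_ols(X, y)
  expect_equal(unname(f$coefficients), c(5, 0, 0), tolerance = 1e-12)
  expect_equal(f$pseudo_r2, 0)
})

test_that("rank deficiency is refused", {
  X <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(X, rnorm(10)), "rank deficient")
})

test_that("Moran's I is exactly -1 on a rook checkerboard", {
  for (side in c(4, 6)) {
    W <- lattice_weights(side, side, type = "rook")
    rc <- expand.grid(col = 1:side, row = 1:side)
    e <- (-1)^(rc$row + rc$col)
    m <- morans_i(e, W)
    expect_equal(m$I, -1, tolerance = 1e-12)
    expect_lt(m$z, 0)
  }
})

test_that("Moran's I mean under iid residuals matches -1/(n-1)", {
  W <- lattice_weights(10, 10)
  set.seed(33)
  Is <- vapply(1:500, function(b) morans_i(rnorm(100), W)$I, numeric(1))
  mc_se <- sd(Is) / sqrt(500)
  expect_lt(abs(mean(Is) - (-1 / 99)), 3 * mc_se)
})

test_that("Moran permutation inference is deterministic under seed", {
  W <- lattice_weights(5, 5)
  set.seed(4)
  e <- rnorm(25)
  m1 <- morans_i(e, W, scheme = "permutation", n_perm = 199, seed = 77)
  m2 <- morans_i(e, W, scheme = "permutation", n_perm = 199, seed = 77)
  expect_identical(m1$p, m2$p)
  expect_identical(m1$variance, m2$variance)
  expect_equal(m1$I, morans_i(e, W)$I)
})

test_that("Moran's I is scale invariant and rejects degenerate input", {
  W <- lattice_weights(4, 4)
  set.seed(6)
  e <- rnorm(16)
  expect_equal(morans_i(e, W)$I, morans_i(-3.7 * e, W)$I, tolerance = 1e-12)
  expect_error(morans_i(rep(1, 16), W), "constant")
})

test_that("the Moran gate fires under a strongly lagged process", {
  W <- lattice_weights(20, 20)
  set.seed(15)
  dgp <- make_dgp(W, k = 3, par = 0.7, process = "lag")
  hits <- 0L
  for (b in 1:20) {
    y <- dgp$draw()
    res <- fit_ols(dgp$X, y)$residuals
    if (morans_i(res, W)$z > 2) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("VIF matches its definition and detects collinearity", {
  # orthogonal balanced design: all VIF exactly 1
  X <- cbind(a = rep(c(-1, 1), 8), b = rep(c(-1, -1, 1, 1), 4),
             c = rep(c(-1, 1), each = 8))
  expect_equal(vif(X)$vif, rep(1, 3), tolerance = 1e-12)
  # duplicated column: infinite, flagged
  Xd <- cbind(a = rnorm(30), b = rnorm(30))
  Xd <- cbind(Xd, c = Xd[, "a"])
  expect_warning(v <- vif(Xd), "collinearity")
  expect_true(is.infinite(v$vif[v$variable == "c"]))
  # near-collinear column agrees with a standalone auxiliary regression
  set.seed(20)
  x1 <- rnorm(100); x2 <- rnorm(100)
  x3 <- x1 + x2 + rnorm(100, sd = 0.1)
  Xn <- cbind(x1 = x1, x2 = x2, x3 = x3)
  aux <- summary(lm(x3 ~ x1 + x2))$r.squared
  expect_equal(vif(Xn)$vif[3], 1 / (1 - aux), tolerance = 1e-10)
})
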