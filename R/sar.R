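# Maximum-likelihood spatial lag and spatial error regressions.
#
# Both estimators profile beta and sigma^2 out of the Gaussian likelihood
# and maximize a one-dimensional concentrated log-likelihood over the
# spatial parameter, with the Jacobian term ln|I - par*W| evaluated from
# the (real) eigenvalue spectrum of the row-standardized W:
#   ln|I - par*W| = sum_i ln(1 - par * omega_i).
# Standard errors come from the numeric Hessian of the full log-likelihood
# at the optimum (central differences).

# shared pre-flight: dense W, spectrum, lagged quantities
sar_prepare <- function(X, y, W, intercept) {
  stopifnot(inherits(W, "spatial_weights"))
  if (W$style != "W") stopf("W must be row-standardized (use row_standardize)")
  if (length(W$islands) > 0L) {
    stopf("W contains %d island(s); exclude them before estimation",
          length(W$islands))
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n || W$n != n) stopf("X, y and W disagree on n")
  X1 <- design_with_constant(X, intercept)
  if (qr(X1)$rank < ncol(X1)) stopf("design matrix is rank deficient")
  if (n <= ncol(X1) + 2L) stopf("too few observations for ML estimation")
  Wm <- weights_matrix(W)
  ev <- eigenvalue_bounds(W)
  list(X1 = X1, y = y, n = n, k = ncol(X1), Wm = Wm,
       omega = ev$values, lo = 1 / ev$min, hi = 1 / ev$max)
}

# bounded scalar maximization of the concentrated log-likelihood
sar_optimize <- function(conc, lo, hi, delta = 1e-5, tol = 1e-9) {
  opt <- stats::optimize(conc, lower = lo + delta, upper = hi - delta,
                         maximum = TRUE, tol = tol)
  par <- opt$maximum
  converged <- par > lo + delta + 1e-4 && par < hi - delta - 1e-4
  if (!converged) {
    warnf("spatial parameter estimate %.4f sits at the interval boundary; \
flagging non-convergence", par)
  }
  list(par = par, value = opt$objective, converged = converged)
}

# central-difference Hessian; documented step h_i = eps^(1/4) * max(|x_i|, 0.01)
num_hessian <- function(f, x) {
  p <- length(x)
  h <- .Machine$double.eps^0.25 * pmax(abs(x), 0.01)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# standard errors for (beta, spatial par) from the full-likelihood Hessian;
# sigma^2 is included in the parameterization and dropped from the report
sar_se <- function(loglik_fn, theta, k) {
  H <- num_hessian(loglik_fn, theta)
  V <- try(solve(-H), silent = TRUE)
  if (inherits(V, "try-error") || any(diag(as.matrix(V))[1:(k + 1)] < 0)) {
    warnf("singular or indefinite Hessian; standard errors unavailable")
    return(rep(NA_real_, k + 1))
  }
  sqrt(diag(V)[1:(k + 1)])
}

#' Maximum-likelihood spatial lag model
#'
#' Fits `y = rho W y + X beta + eps`, `eps ~ N(0, sigma^2 I)`, by full
#' maximum likelihood. `rho` maximizes the concentrated log-likelihood
#' `const - (n/2) ln(e(rho)'e(rho)/n) + sum_i ln(1 - rho omega_i)` where
#' `e(rho)` are the OLS residuals of `y - rho W y` on X; because both
#' residual vectors are precomputed, the residual sum of squares is an
#' exact quadratic in `rho` and each likelihood evaluation is O(n).
#' Predictions are the reduced form `(I - rho W)^-1 X beta`; R-squared is
#' the squared correlation of observed and predicted.
#'
#' @param X predictor matrix (no intercept column).
#' @param y outcome vector.
#' @param W row-standardized, island-free `spatial_weights`.
#' @param intercept add a constant (default `TRUE`).
#' @param compute_se evaluate the numeric-Hessian standard errors (default
#'   `TRUE`; disable in tight simulation loops).
#' @return a `greensar_fit` of kind `"lag"` with fields `rho`, `rho_se`,
#'   coefficient table, `loglik`, `aic`, `pseudo_r2`.
#' @export
fit_spatial_lag <- function(X, y, W, intercept = TRUE, compute_se = TRUE) {
  pr <- sar_prepare(X, y, W, intercept)
  wy <- drop(pr$Wm %*% pr$y)
  qx <- qr(pr$X1)
  e0 <- qr.resid(qx, pr$y)
  eL <- qr.resid(qx, wy)
  a <- sum(e0^2); b <- sum(e0 * eL); cc <- sum(eL^2)
  n <- pr$n
  const <- -n / 2 * (log(2 * pi) + 1)
  conc <- function(rho) {
    sse <- a - 2 * b * rho + cc * rho^2
    const - n / 2 * log(sse / n) + sum(log(1 - rho * pr$omega))
  }
  opt <- sar_optimize(conc, pr$lo, pr$hi)
  rho <- opt$par
  beta <- qr.coef(qx, pr$y - rho * wy)
  sse <- a - 2 * b * rho + cc * rho^2
  sigma2 <- sse / n
  loglik <- opt$value

  full_ll <- function(theta) {
    bet <- theta[seq_len(pr$k)]
    r <- theta[pr$k + 1]
    s2 <- theta[pr$k + 2]
    if (s2 <= 0 || r <= pr$lo || r >= pr$hi) return(-Inf)
    e <- pr$y - r * wy - drop(pr$X1 %*% bet)
    -n / 2 * log(2 * pi * s2) + sum(log(1 - r * pr$omega)) -
      sum(e^2) / (2 * s2)
  }
  if (compute_se) {
    se_all <- sar_se(full_ll, c(beta, rho, sigma2), pr$k)
    se <- stats::setNames(se_all[seq_len(pr$k)], names(beta))
    rho_se <- se_all[pr$k + 1]
  } else {
    se <- stats::setNames(rep(NA_real_, pr$k), names(beta))
    rho_se <- NA_real_
  }
  fitted <- drop(solve(diag(n) - rho * pr$Wm, drop(pr$X1 %*% beta)))
  fit <- new_model_fit(
    kind = "lag", coefficients = beta, se = se, sigma2 = sigma2,
    loglik = loglik, aic = 2 * (pr$k + 2) - 2 * loglik,
    pseudo_r2 = squared_cor(pr$y, fitted),
    residuals = pr$y - rho * wy - drop(pr$X1 %*% beta),
    fitted = fitted, n = n, k = pr$k,
    rho = rho, rho_se = rho_se, converged = opt$converged
  )
  fit$std_beta <- standardized_coefficients(fit, pr$X1, pr$y)
  fit
}

#' Maximum-likelihood spatial error model
#'
#' Fits `y = X beta + eps`, `eps = lambda W eps + u`, `u ~ N(0, sigma^2 I)`,
#' by full maximum likelihood. `lambda` maximizes the concentrated
#' log-likelihood of the spatially filtered regression of
#' `(I - lambda W) y` on `(I - lambda W) X` plus the Jacobian term
#' `sum_i ln(1 - lambda omega_i)`; `beta` is the GLS estimate at the
#' optimal `lambda`. Predictions are the trend `X beta`.
#'
#' @inheritParams fit_spatial_lag
#' @return a `greensar_fit` of kind `"error"` with fields `lambda`,
#'   `rho_se` (its standard error), coefficient table, `loglik`, `aic`,
#'   `pseudo_r2`.
#' @export
fit_spatial_error <- function(X, y, W, intercept = TRUE, compute_se = TRUE) {
  pr <- sar_prepare(X, y, W, intercept)
  wy <- drop(pr$Wm %*% pr$y)
  WX <- pr$Wm %*% pr$X1
  n <- pr$n
  const <- -n / 2 * (log(2 * pi) + 1)
  gls_at <- function(lambda) {
    ys <- pr$y - lambda * wy
    Xs <- pr$X1 - lambda * WX
    f <- stats::lm.fit(Xs, ys)
    list(beta = f$coefficients, sse = sum(f$residuals^2))
  }
  conc <- function(lambda) {
    sse <- gls_at(lambda)$sse
    const - n / 2 * log(sse / n) + sum(log(1 - lambda * pr$omega))
  }
  opt <- sar_optimize(conc, pr$lo, pr$hi)
  lambda <- opt$par
  g <- gls_at(lambda)
  beta <- g$beta
  sigma2 <- g$sse / n
  loglik <- opt$value

  full_ll <- function(theta) {
    bet <- theta[seq_len(pr$k)]
    l <- theta[pr$k + 1]
    s2 <- theta[pr$k + 2]
    if (s2 <= 0 || l <= pr$lo || l >= pr$hi) return(-Inf)
    eps <- pr$y - drop(pr$X1 %*% bet)
    u <- eps - l * drop(pr$Wm %*% eps)
    -n / 2 * log(2 * pi * s2) + sum(log(1 - l * pr$omega)) -
      sum(u^2) / (2 * s2)
  }
  if (compute_se) {
    se_all <- sar_se(full_ll, c(beta, lambda, sigma2), pr$k)
    se <- stats::setNames(se_all[seq_len(pr$k)], names(beta))
    lambda_se <- se_all[pr$k + 1]
  } else {
    se <- stats::setNames(rep(NA_real_, pr$k), names(beta))
    lambda_se <- NA_real_
  }
  fitted <- drop(pr$X1 %*% beta)
  fit <- new_model_fit(
    kind = "error", coefficients = beta, se = se, sigma2 = sigma2,
    loglik = loglik, aic = 2 * (pr$k + 2) - 2 * loglik,
    pseudo_r2 = squared_cor(pr$y, fitted),
    residuals = pr$y - fitted, fitted = fitted, n = n, k = pr$k,
    lambda = lambda, rho_se = lambda_se, converged = opt$converged
  )
  fit$std_beta <- standardized_coefficients(fit, pr$X1, pr$y)
  fit
}

#' Concentrated log-likelihood profile of a spatial model
#'
#' Exposes the one-dimensional concentrated log-likelihood the ML
#' estimators maximize, for diagnostics and for grid-search cross-checks.
#'
#' @param X,y,W as in [fit_spatial_lag()].
#' @param kind `"lag"` or `"error"`.
#' @param at numeric vector of spatial-parameter values to evaluate.
#' @param intercept add a constant (default `TRUE`).
#' @return numeric vector of log-likelihood values at `at` (`-Inf` outside
#'   the admissible interval).
#' @export
concentrated_loglik <- function(X, y, W, kind = c("lag", "error"), at,
                                intercept = TRUE) {
  kind <- match.arg(kind)
  pr <- sar_prepare(X, y, W, intercept)
  n <- pr$n
  const <- -n / 2 * (log(2 * pi) + 1)
  wy <- drop(pr$Wm %*% pr$y)
  if (kind == "lag") {
    qx <- qr(pr$X1)
    e0 <- qr.resid(qx, pr$y)
    eL <- qr.resid(qx, wy)
    a <- sum(e0^2); b <- sum(e0 * eL); cc <- sum(eL^2)
    fn <- function(par) {
      sse <- a - 2 * b * par + cc * par^2
      const - n / 2 * log(sse / n) + sum(log(1 - par * pr$omega))
    }
  } else {
    WX <- pr$Wm %*% pr$X1
    fn <- function(par) {
      f <- stats::lm.fit(pr$X1 - par * WX, pr$y - par * wy)
      const - n / 2 * log(sum(f$residuals^2) / n) +
        sum(log(1 - par * pr$omega))
    }
  }
  vapply(at, function(p) {
    if (p <= pr$lo || p >= pr$hi) -Inf else fn(p)
  }, numeric(1))
}
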