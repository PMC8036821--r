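# OLS estimation, Moran's I on residuals and VIF screening: the
# model-selection path that decides between OLS and the spatial models.

new_model_fit <- function(kind, coefficients, se, sigma2, loglik, aic,
                          pseudo_r2, residuals, fitted, n, k,
                          rho = NULL, lambda = NULL, rho_se = NULL,
                          std_beta = NULL, converged = TRUE) {
  z <- coefficients / se
  structure(
    list(kind = kind, coefficients = coefficients, se = se, z = z,
         p = 2 * stats::pnorm(-abs(z)), sigma2 = sigma2,
         rho = rho, lambda = lambda, rho_se = rho_se,
         std_beta = std_beta, loglik = loglik, aic = aic,
         pseudo_r2 = pseudo_r2, residuals = residuals, fitted = fitted,
         n = n, k = k, converged = converged),
    class = "greensar_fit"
  )
}

sig_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "***",
                              ifelse(p < 0.05, "**",
                                     ifelse(p < 0.10, "*", ""))))
}

#' @export
print.greensar_fit <- function(x, ...) {
  label <- switch(x$kind, ols = "OLS", lag = "Spatial lag (ML)",
                  error = "Spatial error (ML)")
  cat(sprintf("%s model, n = %d\n\n", label, x$n))
  tab <- data.frame(
    Coef. = sprintf("%.4f", x$coefficients),
    Standardized = ifelse(is.na(x$std_beta), "", sprintf("%.4f", x$std_beta)),
    S.E. = sprintf("%.4f", x$se),
    Z = sprintf("%s %.3f", sig_stars(x$p), x$z),
    row.names = names(x$coefficients), check.names = FALSE
  )
  print(tab)
  if (!is.null(x$rho)) {
    cat(sprintf("\nLag coefficient (Rho): %.4f (S.E. %.4f)\n",
                x$rho, x$rho_se %||% NA_real_))
  }
  if (!is.null(x$lambda)) {
    cat(sprintf("\nLag coefficient (Lambda): %.4f (S.E. %.4f)\n",
                x$lambda, x$rho_se %||% NA_real_))
  }
  cat(sprintf("R-squared: %.4f   Log likelihood: %.3f   AIC: %.1f\n",
              x$pseudo_r2, x$loglik, x$aic))
  cat("Signif.: *** p<0.01, ** p<0.05, * p<0.10 (2-tailed)\n")
  invisible(x)
}

#' @export
logLik.greensar_fit <- function(object, ...) {
  structure(object$loglik, df = aic_df(object), class = "logLik")
}

# AIC parameter count: all beta + sigma^2 + (one spatial parameter)
aic_df <- function(fit) {
  fit$k + 1L + as.integer(fit$kind %in% c("lag", "error"))
}

#' Log-likelihood and AIC of a fitted model
#'
#' AIC = 2K - 2 logLik with K = (number of regression coefficients
#' including the constant) + 1 for the error variance + 1 for the spatial
#' parameter in the lag/error models. The counting convention is fixed by
#' this documentation.
#'
#' @param fit a fitted model from [fit_ols()], [fit_spatial_lag()] or
#'   [fit_spatial_error()].
#' @return list with `loglik` and `aic`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "greensar_fit"))
  list(loglik = fit$loglik, aic = fit$aic)
}

#' Ordinary least squares fit
#'
#' Baseline estimator of the outcome-on-landscape regression. Reports
#' classical (unbiased-variance) standard errors, the Gaussian maximum
#' log-likelihood, AIC under the documented K convention, standardized
#' coefficients, and R-squared as the squared correlation of observed and
#' fitted values (identical to the usual R-squared with an intercept).
#'
#' @param X numeric matrix of predictors, one column per variable, without
#'   an intercept column.
#' @param y numeric outcome vector.
#' @param intercept add a constant term (default `TRUE`).
#' @return a `greensar_fit` of kind `"ols"`.
#' @examples
#' X <- cbind(a = rnorm(50), b = rnorm(50))
#' y <- 1 + 2 * X[, "a"] - X[, "b"] + rnorm(50)
#' fit_ols(X, y)
#' @export
fit_ols <- function(X, y, intercept = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stopf("X and y disagree on n")
  X1 <- design_with_constant(X, intercept)
  k <- ncol(X1)
  if (n <= k) stopf("need n > number of coefficients")
  qx <- qr(X1)
  if (qx$rank < k) stopf("design matrix is rank deficient")
  beta <- qr.coef(qx, y)
  fitted <- drop(X1 %*% beta)
  res <- y - fitted
  sse <- sum(res^2)
  sigma2_ml <- sse / n
  se <- sqrt(diag(chol2inv(qr.R(qx))) * sse / (n - k))
  loglik <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  fit <- new_model_fit(
    kind = "ols", coefficients = beta, se = se, sigma2 = sigma2_ml,
    loglik = loglik, aic = 2 * (k + 1) - 2 * loglik,
    pseudo_r2 = squared_cor(y, fitted),
    residuals = res, fitted = fitted, n = n, k = k
  )
  fit$std_beta <- standardized_coefficients(fit, X1, y)
  fit
}

design_with_constant <- function(X, intercept) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (intercept && !"Constant" %in% colnames(X)) {
    X <- cbind(Constant = 1, X)
  }
  X
}

squared_cor <- function(y, yhat) {
  if (stats::sd(yhat) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(y, yhat)^2
}

#' Standardized regression coefficients
#'
#' `std_beta_j = beta_j * sd(x_j) / sd(y)`; the constant has no
#' standardized value (`NA`).
#'
#' @param fit a fitted `greensar_fit` (used for its coefficients).
#' @param X design matrix the model was fitted to (with or without the
#'   constant column).
#' @param y outcome vector.
#' @return named numeric vector aligned with the model coefficients.
#' @export
standardized_coefficients <- function(fit, X, y) {
  stopifnot(inherits(fit, "greensar_fit"))
  X <- as.matrix(X)
  beta <- fit$coefficients
  sdy <- stats::sd(y)
  out <- rep(NA_real_, length(beta))
  names(out) <- names(beta)
  for (j in names(beta)) {
    if (j == "Constant") next
    if (!j %in% colnames(X)) stopf("column '%s' missing from X", j)
    sdx <- stats::sd(X[, j])
    if (sdx == 0) stopf("zero-variance column '%s'", j)
    out[j] <- beta[j] * sdx / sdy
  }
  out
}

#' Moran's I test for spatial autocorrelation of residuals
#'
#' `I = (n / S0) * (z' W z) / (z' z)` with `z` the deviations of the
#' residuals from their mean (for OLS residuals of a model with an
#' intercept, `z` equals the residuals themselves) and expectation
#' `-1/(n-1)` under the null of no spatial autocorrelation. Inference is
#' either analytic under
#' the normality assumption (default, giving the familiar z-score/p-value
#' pair) or by random permutation of the residuals with an empirical
#' two-sided pseudo p-value. A clearly significant Moran's I on OLS
#' residuals is the gate for preferring the spatial models.
#'
#' @param residuals numeric vector (raw OLS residuals, not studentized).
#' @param W a `spatial_weights` object.
#' @param scheme `"normal"` (analytic) or `"permutation"`.
#' @param n_perm number of permutations for the permutation scheme.
#' @param seed RNG seed for the permutation scheme (deterministic p).
#' @return object of class `moran_result`: `I`, `expected`, `variance`,
#'   `z`, `p`, plus `scheme` and (permutation only) `n_perm`.
#' @export
morans_i <- function(residuals, W, scheme = c("normal", "permutation"),
                     n_perm = 999, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(W, "spatial_weights"))
  e <- as.numeric(residuals)
  n <- length(e)
  if (n != W$n) stopf("residuals and W disagree on n")
  if (n < 3L) stopf("Moran's I needs n >= 3")
  if (stats::sd(e) == 0) stopf("residuals are constant; Moran's I undefined")

  lag_of <- function(v) {
    vapply(seq_len(n), function(i) {
      nb <- W$neighbours[[i]]
      if (length(nb) == 0L) 0 else sum(W$weights[[i]] * v[nb])
    }, numeric(1))
  }
  s0 <- sum(unlist(W$weights))
  I_of <- function(v) {
    z <- v - mean(v)
    (n / s0) * sum(z * lag_of(z)) / sum(z^2)
  }
  I <- I_of(e)  # raw residuals (not studentized), centered by definition
  expected <- -1 / (n - 1)

  if (scheme == "normal") {
    # S1, S2 moments of W under the normality assumption
    wm <- weights_matrix(W)
    s1 <- 0.5 * sum((wm + t(wm))^2)
    s2 <- sum((rowSums(wm) + colSums(wm))^2)
    variance <- (n^2 * s1 - n * s2 + 3 * s0^2) /
      (s0^2 * (n^2 - 1)) - expected^2
    if (variance <= 0) stopf("degenerate W: non-positive Moran variance")
    z <- (I - expected) / sqrt(variance)
    p <- 2 * stats::pnorm(-abs(z))
    res <- list(I = I, expected = expected, variance = variance,
                z = z, p = p, scheme = scheme)
  } else {
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) I_of(sample(e)), numeric(1))
    })
    variance <- stats::var(perm)
    z <- (I - expected) / sqrt(variance)
    p <- min(1, 2 * (1 + sum(abs(perm - expected) >= abs(I - expected))) /
               (n_perm + 1))
    res <- list(I = I, expected = expected, variance = variance,
                z = z, p = p, scheme = scheme, n_perm = n_perm)
  }
  structure(res, class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf(
    "Moran's I: %.4f (expected %.4f), z = %.3f, p = %.4g [%s]\n",
    x$I, x$expected, x$z, x$p, x$scheme
  ))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor `j` on all other
#' predictors (each auxiliary regression includes an intercept). Exact
#' collinearity yields `Inf` with the offending column identified. The
#' conventional screening rule keeps all VIFs below 5.
#'
#' @param X numeric matrix of predictors (no intercept column); at least
#'   two columns.
#' @return data.frame with columns `variable` and `vif`.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  k <- ncol(X)
  if (k < 2L) stopf("VIF needs at least two predictors")
  if (nrow(X) <= k) stopf("VIF needs n > number of predictors")
  out <- data.frame(variable = colnames(X), vif = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Zj, yj)
    sst <- sum((yj - mean(yj))^2)
    if (sst == 0) stopf("zero-variance predictor '%s'", colnames(X)[j])
    r2 <- 1 - sum(fit$residuals^2) / sst
    out$vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(is.infinite(out$vif))) {
    warnf("exact collinearity detected: %s",
          paste(out$variable[is.infinite(out$vif)], collapse = ", "))
  }
  out
}
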