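#' Maximum-likelihood logistic fit with explicit failure flags
#'
#' Fits a binomial-logit GLM by iteratively reweighted least squares with a
#' fixed convergence contract: relative log-likelihood change below `tol`,
#' at most `maxit` iterations, quasi-separation flagged when any coefficient
#' exceeds `sepThreshold` on the log-odds scale, and rank-deficient designs
#' flagged `degenerate` (no silent pseudo-inverse fits). Per-term p-values
#' are Wald tests.
#'
#' @param X numeric design matrix including the intercept column.
#' @param y binary 0/1 outcome with both classes present.
#' @param maxit maximum IRLS iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param sepThreshold log-odds magnitude beyond which a coefficient is
#'   treated as evidence of (quasi-)separation.
#' @return list with `coefficients`, `se`, `z`, `p`, `logLik`, `bic`, `k`,
#'   `n`, `iter` and the flags `converged`, `separated`, `degenerate`.
#' @examples
#' y <- rep(0:1, 50)
#' f <- fitLogistic(cbind(1, rnorm(100)), y)
#' f$p
#' @export
fitLogistic <- function(X, y, maxit = 50L, tol = 1e-8, sepThreshold = 15) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (!all(is.finite(X))) stop("design columns must be finite")
  f <- .fit_logistic_cpp(X, y, as.integer(maxit), tol, sepThreshold)
  k <- ncol(X)
  n <- nrow(X)
  cf <- f$coefficients
  se <- f$se
  z <- cf / se
  names(cf) <- names(se) <- names(z) <-
    if (!is.null(colnames(X))) colnames(X) else paste0("b", seq_len(k) - 1L)
  list(coefficients = cf, se = se, z = z, p = 2 * pnorm(-abs(z)),
       logLik = f$logLik, bic = k * log(n) - 2 * f$logLik, k = k, n = n,
       iter = f$iter, converged = f$converged, separated = f$separated,
       degenerate = f$degenerate)
}

## log-likelihood of the intercept-only binomial model
.nullLogLik <- function(y) {
  n <- length(y)
  p <- mean(y)
  if (p <= 0 || p >= 1) return(0)
  n * (p * log(p) + (1 - p) * log(1 - p))
}
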