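#' Restricted likelihood of the one-component genomic model at a given
#' variance ratio
#'
#' Profile REML log-likelihood of \eqn{y = X\beta + g + e}, with
#' \eqn{g \sim N(0, K\sigma^2_a)} and \eqn{e \sim N(0, I\sigma^2_e)},
#' profiled over \eqn{\sigma^2_a} at fixed ratio
#' \eqn{\delta = \sigma^2_e/\sigma^2_a}. Exposed so optimiser output can
#' be compared against a grid search.
#'
#' @param delta variance ratio (vectorised).
#' @param y response vector.
#' @param K kinship / genomic relationship matrix.
#' @param X fixed-effect design (default intercept).
#' @return numeric vector of restricted log-likelihoods.
#' @export
reml_loglik <- function(delta, y, K, X = NULL) {
  sp <- reml_spectral(y, K, X)
  vapply(delta, function(d) reml_ll_from_spectral(d, sp), numeric(1))
}

## eigen-structure of the fixed-effect-projected kinship, reused across
## likelihood evaluations
reml_spectral <- function(y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stopifnot(nrow(K) == n, ncol(K) == n, nrow(X) == n)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]] %||%
      qx$pivot[seq(qx$rank + 1, ncol(X))]
    stop("fixed-effect design is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  p <- ncol(X)
  ## orthonormal basis of the complement of span(X): correct for singular K
  ## (e.g. genotype-incidence kinships), where eigenvalue ordering cannot
  ## separate null(S) from genuine zero-variance directions
  Kb <- qr.Q(qx, complete = TRUE)[, -seq_len(p), drop = FALSE]
  A <- crossprod(Kb, K %*% Kb)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  q <- n - p
  xi <- pmax(e$values, 0)
  eta <- drop(crossprod(e$vectors, crossprod(Kb, y)))
  list(xi = xi, eta = eta, q = q, X = X, n = n)
}

reml_ll_from_spectral <- function(delta, sp) {
  w <- sp$xi + delta
  ss <- sum(sp$eta^2 / w)
  0.5 * (sp$q * (log(sp$q / (2 * pi)) - 1 - log(ss)) - sum(log(w)))
}

#' Single-trait REML by profiled spectral decomposition
#'
#' Estimates the additive and residual variance of
#' \eqn{y = X\beta + g + e}, \eqn{g \sim N(0, K\sigma^2_a)}, by a bounded
#' Brent search of the profiled restricted likelihood over
#' \eqn{\log\delta}, \eqn{\delta = \sigma^2_e/\sigma^2_a}. The spectral
#' decomposition of the projected kinship makes each likelihood evaluation
#' O(n).
#'
#' @param y response vector (genotype-level BLUEs).
#' @param K genomic relationship matrix (conditioned PSD), n x n. If it
#'   carries the \code{denom} attribute of \code{\link{compute_grm}}, the
#'   marker-effect variance \eqn{\sigma^2_u = \sigma^2_a/denom} and marker
#'   ridge parameter are also reported.
#' @param X optional fixed-effect design matrix (intercept added when
#'   omitted).
#' @param bounds search bounds for \eqn{\log\delta}.
#' @param tol Brent tolerance.
#' @return object of class \code{gs_reml}: sigma2_a, sigma2_e, delta,
#'   lambda (= delta, the G-scale ridge), sigma2_u / lambda_marker when
#'   available, h2, beta, loglik, boundary flag.
#' @export
reml_single_trait <- function(y, K, X = NULL, bounds = c(-10, 10), tol = 1e-8) {
  y <- drop(y)
  n <- length(y)
  if (n < 10) stop("need at least 10 observations for REML")
  if (stats::sd(y) == 0) stop("response has zero variance")
  sp <- reml_spectral(y, K, X)
  obj <- function(ld) reml_ll_from_spectral(exp(ld), sp)
  opt <- stats::optimize(obj, interval = bounds, maximum = TRUE, tol = tol)
  ## guard against a maximum at the boundary that Brent cannot bracket
  cand <- rbind(c(opt$maximum, opt$objective),
                c(bounds[1], obj(bounds[1])),
                c(bounds[2], obj(bounds[2])))
  best <- cand[which.max(cand[, 2]), ]
  ld <- best[1]
  if (!is.finite(best[2])) stop("non-finite restricted likelihood; check K conditioning")
  delta <- exp(ld)
  boundary <- ld <= bounds[1] + 1e-3 || ld >= bounds[2] - 1e-3
  w <- sp$xi + delta
  sigma2_a <- sum(sp$eta^2 / w) / sp$q
  sigma2_e <- delta * sigma2_a
  ## GLS fixed effects at the optimum
  Vi_chol <- chol(K + delta * diag(n))
  Xs <- backsolve(Vi_chol, sp$X, transpose = TRUE)
  ys <- backsolve(Vi_chol, y, transpose = TRUE)
  beta <- drop(solve(crossprod(Xs), crossprod(Xs, ys)))
  denom <- attr(K, "denom")
  ## per-line genetic variance is diag(K)_i * sigma2_a; for inbred panels
  ## the VanRaden diagonal is near 1 + F, so h2 uses the mean diagonal
  kbar <- mean(diag(K))
  out <- list(sigma2_a = sigma2_a, sigma2_e = sigma2_e, delta = delta,
              lambda = delta, sigma2_g = kbar * sigma2_a,
              h2 = max(0, min(1, kbar * sigma2_a / (kbar * sigma2_a + sigma2_e))),
              beta = beta, loglik = best[2], boundary = boundary,
              n = n)
  if (!is.null(denom)) {
    out$sigma2_u <- sigma2_a / denom
    out$lambda_marker <- sigma2_e / out$sigma2_u
  }
  class(out) <- "gs_reml"
  out
}

#' @export
print.gs_reml <- function(x, ...) {
  cat("Single-trait REML (profiled spectral)\n")
  cat(sprintf("  sigma2_a = %.5g, sigma2_e = %.5g, delta = %.5g\n",
              x$sigma2_a, x$sigma2_e, x$delta))
  cat(sprintf("  h2 = %.4f, restricted logLik = %.4f%s\n", x$h2, x$loglik,
              if (x$boundary) "  [boundary]" else ""))
  invisible(x)
}

## solve the training system once; returns the weight vector alpha with
## g_hat(new) = K[new, train] %*% alpha
gblup_alpha <- function(fit, K_train, y_train, X_train = NULL) {
  n <- length(y_train)
  if (is.null(X_train)) X_train <- matrix(1, n, 1)
  resid <- y_train - drop(as.matrix(X_train) %*% fit$beta)
  solve(K_train + fit$delta * diag(n), resid)
}
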