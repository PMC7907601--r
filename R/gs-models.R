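#' Ridge-regression BLUP of marker effects
#'
#' Closed-form rrBLUP solution on the mean-centred response:
#' \eqn{u = Z'(ZZ' + \lambda I)^{-1} y_c}, \eqn{\lambda =
#' \sigma^2_e/\sigma^2_u}. GEBVs are \eqn{Zu} for any line with genotypes.
#'
#' @param y response vector (training lines).
#' @param Z marker matrix of the training lines (typically column-centred
#'   dosages).
#' @param lambda ridge parameter (> 0), usually from
#'   \code{\link{reml_single_trait}}.
#' @return list: \code{u} marker effects, \code{gebv} training GEBVs
#'   (centred), \code{intercept} the removed mean, \code{lambda}.
#' @export
solve_rrblup <- function(y, Z, lambda) {
  y <- drop(y)
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == length(y))
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  mu <- mean(y)
  yc <- y - mu
  n <- length(y)
  A <- tcrossprod(Z) + lambda * diag(n)
  u <- drop(crossprod(Z, solve(A, yc)))
  list(u = u, gebv = drop(Z %*% u), intercept = mu, lambda = lambda)
}

#' Multiple regression of a trait on spectral indices
#'
#' Ordinary least squares with intercept; the phenomic-only prediction
#' model. Collinear index columns are an error naming the dependent
#' columns.
#'
#' @param y response vector.
#' @param X_sri numeric matrix of index values (lines x indices).
#' @return object of class \code{gs_srir}: coefficients, fitted values,
#'   residuals.
#' @export
fit_sri_regression <- function(y, X_sri) {
  y <- drop(y)
  X_sri <- as.matrix(X_sri)
  stopifnot(nrow(X_sri) == length(y))
  if (length(y) <= ncol(X_sri) + 1)
    stop("need n > number of indices + 1 observations")
  X <- cbind(`(Intercept)` = 1, X_sri)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("collinear index columns: ", paste(dep, collapse = ", "))
  }
  beta <- drop(qr.coef(qx, y))
  fitted <- drop(X %*% beta)
  structure(list(coefficients = beta, fitted.values = fitted,
                 residuals = y - fitted, n = length(y)),
            class = "gs_srir")
}

#' @export
predict.gs_srir <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  drop(cbind(1, X_new) %*% object$coefficients)
}

#' Genomic prediction with fixed spectral-index covariates
#'
#' REML of \eqn{y = X\beta + g + e} with the indices (plus intercept) as
#' fixed effects, absorbed by projection inside the profiled spectral
#' REML; then GLS fixed effects and BLUP genetic values at the optimum.
#' Prediction for an unphenotyped line is \eqn{x'\hat\beta + \hat g}.
#'
#' @param y response vector (training lines).
#' @param X_sri index matrix of the training lines.
#' @param K genomic relationship matrix of the training lines.
#' @return object of class \code{gs_covfit}: the REML fit (\code{vc}),
#'   \code{beta}, training GEBVs, and the BLUP weight vector for
#'   prediction.
#' @export
fit_covariate_gs <- function(y, X_sri, K) {
  y <- drop(y)
  X <- cbind(`(Intercept)` = 1, as.matrix(X_sri))
  vc <- reml_single_trait(y, K, X = X)
  alpha <- gblup_alpha(vc, K, y, X)
  structure(list(vc = vc, beta = stats::setNames(vc$beta, colnames(X)),
                 gebv = drop(K %*% alpha), alpha = alpha,
                 n = length(y)), class = "gs_covfit")
}

#' @export
#' @rdname fit_covariate_gs
#' @param object a \code{gs_covfit}.
#' @param K_cross relationship block, new lines x training lines.
#' @param X_new index matrix of the new lines.
#' @param include_fixed add \eqn{x'\hat\beta} to the genetic value
#'   (default TRUE: the model's phenotype-scale prediction).
#' @param ... unused.
predict.gs_covfit <- function(object, K_cross, X_new = NULL,
                              include_fixed = TRUE, ...) {
  g <- drop(as.matrix(K_cross) %*% object$alpha)
  if (include_fixed) {
    if (is.null(X_new)) stop("X_new needed when include_fixed = TRUE")
    g <- g + drop(cbind(1, as.matrix(X_new)) %*% object$beta)
  }
  g
}
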