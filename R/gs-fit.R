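#' Fit a genomic / phenomic prediction model
#'
#' The package's central fitting function. Four models are available,
#' mirroring the standard single- and multi-trait genomic selection
#' toolkit:
#' \describe{
#'   \item{unigs}{univariate GBLUP / rrBLUP: \eqn{y = \mu + Zu + e},
#'     variance components by profiled spectral REML.}
#'   \item{srir}{phenomic-only multiple regression of the trait on the
#'     spectral indices.}
#'   \item{gs_sri}{GBLUP with the indices as fixed covariates:
#'     \eqn{y = \mu + X\beta + Zu + e}.}
#'   \item{multigs}{multi-trait GBLUP treating the indices as correlated
#'     response traits, unstructured H and R by EM-REML; prediction for
#'     unphenotyped lines conditions on their observed indices.}
#' }
#'
#' @param y named vector of genotype-level values of the primary trait
#'   (BLUEs). For multigs, lines with NA are predicted from their
#'   secondary traits.
#' @param K genomic relationship matrix (e.g. \code{\link{compute_grm}});
#'   alternatively supply \code{markers} and K is computed.
#' @param markers optional dosage matrix used to build K (imputed first).
#' @param sri matrix of secondary-trait values (lines x indices) for the
#'   srir / gs_sri / multigs models.
#' @param model model tag, see above.
#' @param stage optional growth-stage label carried to outputs.
#' @param ... passed to the underlying fitter.
#' @return object of class \code{gs_fit} (and a model subclass) with
#'   methods \code{print}, \code{summary}, \code{coef}, \code{fitted},
#'   \code{residuals}, \code{predict}.
#' @seealso \code{\link{reml_single_trait}}, \code{\link{solve_rrblup}},
#'   \code{\link{fit_sri_regression}}, \code{\link{fit_covariate_gs}},
#'   \code{\link{fit_multitrait_gs}}, \code{\link{kfold_cv}}
#' @export
gs_fit <- function(y, K = NULL, markers = NULL, sri = NULL,
                   model = c("unigs", "srir", "gs_sri", "multigs"),
                   stage = NULL, ...) {
  model <- match.arg(model)
  if (is.null(K)) {
    if (is.null(markers)) stop("supply K or markers")
    K <- compute_grm(impute_missing(as.matrix(markers)))
  }
  y <- drop(y)
  if (model != "srir") stopifnot(nrow(K) == length(y))
  if (model %in% c("srir", "gs_sri", "multigs")) {
    if (is.null(sri)) stop("model ", model, " needs sri values")
    sri <- as.matrix(sri)
  }
  obs <- !is.na(y)
  inner <- switch(model,
    unigs = {
      vc <- reml_single_trait(y[obs], K[obs, obs, drop = FALSE], ...)
      alpha <- gblup_alpha(vc, K[obs, obs, drop = FALSE], y[obs])
      gebv <- drop(K[, obs, drop = FALSE] %*% alpha)
      list(vc = vc, gebv = gebv, mu = vc$beta[1])
    },
    srir = fit_sri_regression(y[obs], sri[obs, , drop = FALSE], ...),
    gs_sri = fit_covariate_gs(y[obs], sri[obs, , drop = FALSE],
                              K[obs, obs, drop = FALSE], ...),
    multigs = fit_multitrait_gs(cbind(primary = y, sri), K, ...))
  structure(list(model = model, fit = inner, y = y, K = K, sri = sri,
                 stage = stage, obs = obs, call = match.call()),
            class = c(paste0("gs_fit_", model), "gs_fit"))
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("Genomic selection model fit:", x$model,
      if (!is.null(x$stage)) paste0("(stage: ", x$stage, ")") else "", "\n")
  cat(sprintf("  %d lines (%d phenotyped)\n", length(x$y), sum(x$obs)))
  print(x$fit)
  invisible(x)
}

#' @export
summary.gs_fit <- function(object, ...) {
  g <- fitted(object)
  cat("Model:", object$model, "\n")
  print(object$fit)
  if (!is.null(g)) {
    r <- stats::cor(g[object$obs], object$y[object$obs])
    cat(sprintf("  in-sample correlation of predictions with phenotypes: %.3f\n", r))
  }
  invisible(object)
}

#' @export
coef.gs_fit <- function(object, ...) {
  switch(object$model,
         unigs = c(`(Intercept)` = unname(object$fit$mu)),
         srir = object$fit$coefficients,
         gs_sri = object$fit$beta,
         multigs = object$fit$mu)
}

#' @export
fitted.gs_fit <- function(object, ...) {
  f <- rep(NA_real_, length(object$y))
  names(f) <- names(object$y)
  switch(object$model,
         unigs = f <- object$fit$gebv + unname(object$fit$mu),
         srir = f[object$obs] <- object$fit$fitted.values,
         gs_sri = f[object$obs] <- object$fit$gebv +
           drop(cbind(1, object$sri[object$obs, , drop = FALSE]) %*%
                  object$fit$beta),
         multigs = f <- object$fit$gebv[, 1] + object$fit$mu[1])
  f
}

#' @export
residuals.gs_fit <- function(object, ...) {
  object$y - fitted(object)
}

#' Predict genetic values for new lines
#'
#' @param object a \code{\link{gs_fit}}.
#' @param K_cross relationship block, new lines x training lines (for
#'   unigs / gs_sri).
#' @param sri_new secondary-trait matrix of the new lines.
#' @param include_fixed for gs_sri, add the fixed index part.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gs_fit <- function(object, K_cross = NULL, sri_new = NULL,
                           include_fixed = TRUE, ...) {
  switch(object$model,
    unigs = {
      if (is.null(K_cross)) return(object$fit$gebv)
      fit <- object$fit$vc
      alpha <- gblup_alpha(fit, object$K[object$obs, object$obs, drop = FALSE],
                           object$y[object$obs])
      drop(as.matrix(K_cross) %*% alpha)
    },
    srir = {
      if (is.null(sri_new)) return(stats::fitted(object))
      predict(object$fit, sri_new)
    },
    gs_sri = {
      if (is.null(K_cross)) return(object$fit$gebv)
      predict(object$fit, K_cross, sri_new, include_fixed = include_fixed)
    },
    multigs = {
      object$fit$gebv[, 1]
    })
}
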