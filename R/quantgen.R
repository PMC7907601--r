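#' Narrow-sense heritability from a genomic relationship matrix
#'
#' Animal-model REML \eqn{y = Xb + g + e}, \eqn{g \sim N(0, G\sigma^2_a)};
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)}. Delegates to
#' \code{\link{reml_single_trait}}.
#'
#' @param y genotype-level trait values (BLUEs), one per line.
#' @param K genomic relationship matrix.
#' @param X optional fixed-effect design.
#' @return list of class \code{genetic_params}: h2, sigma2_a, sigma2_e,
#'   boundary flag.
#' @export
narrow_sense_h2 <- function(y, K, X = NULL) {
  fit <- reml_single_trait(y, K, X = X)
  structure(list(h2 = fit$h2, sigma2_a = fit$sigma2_a, sigma2_e = fit$sigma2_e,
                 boundary = fit$boundary, fit = fit),
            class = "genetic_params")
}

#' Genetic correlation between two traits
#'
#' Bivariate animal-model REML (EM, unstructured H and R; delegates to
#' \code{\link{fit_multitrait_gs}}); \eqn{r_G = cov_A(A,B) /
#' \sqrt{var_A(A) var_A(B)}} from the genetic covariance matrix H,
#' clamped to [-1, 1] with a boundary flag when the estimate overshoots.
#'
#' @param yA,yB trait vectors over the same lines.
#' @param K genomic relationship matrix.
#' @param ... passed to \code{\link{fit_multitrait_gs}}.
#' @return list of class \code{genetic_params}: r_G, boundary flag, H, R.
#' @export
genetic_correlation <- function(yA, yB, K, ...) {
  Y <- cbind(A = drop(yA), B = drop(yB))
  fit <- fit_multitrait_gs(Y, K, ...)
  structure(list(r_G = fit$rg[1, 2], boundary = fit$rg_boundary[1, 2],
                 H = fit$H, R = fit$R, fit = fit),
            class = "genetic_params")
}

#' Phenotypic correlation with significance stars
#'
#' Pearson correlation of genotype-level values with the two-sided t-test;
#' stars follow the usual convention (* p<0.05, ** p<0.01, *** p<0.001).
#'
#' @param x,y numeric vectors (paired genotype-level trait values).
#' @return list of class \code{genetic_params}: r_P, p_value, stars, n.
#' @export
phenotypic_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  ct <- stats::cor.test(x[ok], y[ok])
  p <- ct$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  structure(list(r_P = unname(ct$estimate), p_value = p, stars = stars,
                 n = sum(ok)),
            class = "genetic_params")
}

#' @export
print.genetic_params <- function(x, ...) {
  if (!is.null(x$H2))
    cat(sprintf("H2 = %.4f (sigma2_g = %.4g, sigma2_e = %.4g)%s\n", x$H2,
                x$sigma2_g, x$sigma2_e, if (isTRUE(x$boundary)) " [boundary]" else ""))
  if (!is.null(x$h2))
    cat(sprintf("h2 = %.4f (sigma2_a = %.4g, sigma2_e = %.4g)%s\n", x$h2,
                x$sigma2_a, x$sigma2_e, if (isTRUE(x$boundary)) " [boundary]" else ""))
  if (!is.null(x$r_G))
    cat(sprintf("r_G = %.4f%s\n", x$r_G,
                if (isTRUE(x$boundary)) " [boundary, clamped]" else ""))
  if (!is.null(x$r_P))
    cat(sprintf("r_P = %.4f%s (p = %.3g, n = %d)\n", x$r_P, x$stars,
                x$p_value, x$n))
  invisible(x)
}
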