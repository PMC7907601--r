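#' Simulate genetically correlated traits from marker genotypes
#'
#' Inverts the model the downstream analysis assumes: per-marker effect
#' vectors are drawn from a multivariate normal whose covariance induces
#' the configured genetic correlations across traits; true breeding values
#' are \code{TBV = W \%*\% B} with W the column-centred dosage matrix; each
#' trait's genetic values are rescaled so the realised (in-sample) genetic
#' variance equals \code{target_h2} on a unit total-variance scale, and
#' residuals with variance \code{1 - target_h2} and the configured residual
#' correlation are drawn independently per environment. Environment-level
#' mean shifts are added on top.
#'
#' Traits with \code{target_h2 = 0} have all marker effects set to zero;
#' with \code{target_h2 = 1} the phenotype equals the true breeding value.
#'
#' @param markers matrix from \code{\link{simulate_nam_genotypes}} (if
#'   missingness was injected, the complete matrix is used for the truth).
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{values}: data.frame (environment, genotype_id,
#'   is_check, one column per trait) of genotype-level phenotypes, and
#'   \code{truth}: object of class \code{sim_truth} holding
#'   \code{true_breeding_values}, \code{true_marker_effects},
#'   \code{realized_h2} and \code{realized_genetic_corr}.
#' @export
simulate_traits <- function(markers, config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- if (!is.null(attr(markers, "complete"))) attr(markers, "complete") else markers
  if (anyNA(geno))
    stop("markers contain missing values and no complete matrix is attached; impute first")
  tn <- config$trait_names
  t <- length(tn)
  h2 <- config$target_h2
  n <- nrow(geno)
  m <- ncol(geno)
  is_check <- attr(markers, "is_check") %||% rep(FALSE, n)

  set.seed(derive_seed(config$seed, "effects"))
  W <- scale(geno, center = TRUE, scale = FALSE)
  B0 <- matrix(rnorm(m * t), m, t) %*% chol(psd_clip(config$genetic_corr, 1e-10)$mat)
  TBV0 <- W %*% B0
  ## scale so the realised genetic variance among RILs equals h2 (total var 1)
  v0 <- apply(TBV0[!is_check, , drop = FALSE], 2, var)
  sc <- ifelse(h2 > 0 & v0 > 0, sqrt(h2 / v0), 0)
  B <- B0 * rep(sc, each = m)
  TBV <- W %*% B
  colnames(TBV) <- colnames(B) <- tn
  rownames(TBV) <- rownames(geno)

  ## residuals: variance 1 - h2, configured cross-trait correlation
  set.seed(derive_seed(config$seed, "residuals"))
  sd_e <- sqrt(1 - h2)
  Rcov <- diag(sd_e, t) %*% config$residual_corr %*% diag(sd_e, t)
  Rchol <- chol(psd_clip(Rcov, 0)$mat + diag(1e-12, t))
  envs <- sprintf("env%d", seq_len(config$n_environments))
  out <- vector("list", length(envs))
  for (i in seq_along(envs)) {
    E <- matrix(rnorm(n * t), n, t) %*% Rchol
    E[, sd_e == 0] <- 0
    mu_env <- rnorm(t, 0, config$env_mean_sd)
    Y <- TBV + E + rep(mu_env, each = n)
    out[[i]] <- data.frame(environment = envs[i], genotype_id = rownames(geno),
                           is_check = is_check, Y, check.names = FALSE,
                           row.names = NULL)
  }
  values <- do.call(rbind, out)

  truth <- structure(list(
    true_breeding_values = TBV,
    true_marker_effects = B,
    realized_h2 = apply(TBV[!is_check, , drop = FALSE], 2, var) /
      (apply(TBV[!is_check, , drop = FALSE], 2, var) + (1 - h2)),
    realized_genetic_corr = suppressWarnings(
      stats::cor(TBV[!is_check, , drop = FALSE]))),  # NA for h2 = 0 traits
    class = "sim_truth")
  list(values = values, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation ground truth\n")
  cat("  realized h2  :", paste(sprintf("%s=%.3f", names(x$realized_h2),
                                        x$realized_h2), collapse = ", "), "\n")
  if (length(x$realized_h2) > 1) {
    rg <- x$realized_genetic_corr[upper.tri(x$realized_genetic_corr)]
    cat("  realized r_G :", paste(sprintf("%.3f", rg), collapse = ", "), "\n")
  }
  invisible(x)
}
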