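#' Calibration benchmarks on the synthetic NAM population
#'
#' Two pre-registered simulation experiments used to validate the whole
#' pipeline against known ground truth (scales and truth values are fixed
#' design choices, discussed in the methods vignette):
#'
#' \code{benchmark_parameter_recovery} runs, per seed, the full chain
#' simulate genotypes -> simulate traits (two traits, h2 = 0.5 and 0.8,
#' genetic correlation 0.7) -> augmented field layout -> BLUE adjustment
#' -> GRM -> single-trait REML and bivariate EM-REML, on 500 RILs x 2000
#' markers, and reports the estimated heritabilities and genetic
#' correlation next to the realised truth.
#'
#' \code{benchmark_cv_advantage} builds one canonical dataset (600 RILs x
#' 2000 markers; primary trait h2 = 0.3, secondary trait h2 = 0.8,
#' genetic correlation 0.7, residual correlation 0.2) and runs replicated
#' five-fold cross-validation of the univariate, covariate and
#' multi-trait models on it.
#'
#' @param n_seeds number of independent simulated datasets.
#' @param seed root seed.
#' @param n_markers markers per dataset.
#' @return \code{benchmark_parameter_recovery}: data.frame with one row
#'   per seed (estimated and realised h2 for both traits, estimated and
#'   realised genetic correlation). \code{benchmark_cv_advantage}: named
#'   list of \code{\link{kfold_cv}} results (unigs, gs_sri, multigs).
#' @export
benchmark_parameter_recovery <- function(n_seeds = 20, seed = 1,
                                         n_markers = 2000) {
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_families = 25, lines_per_family = 20,
                      n_markers = n_markers,
                      trait_names = c("A", "B"),
                      target_h2 = c(A = 0.5, B = 0.8),
                      genetic_corr = matrix(c(1, .7, .7, 1), 2),
                      n_environments = 1, n_blocks = 12,
                      seed = derive_seed(seed, paste0("recovery", s)))
    dat <- simulate_blue_dataset(cfg)
    h2A <- narrow_sense_h2(dat$Y[, "A"], dat$G)
    h2B <- narrow_sense_h2(dat$Y[, "B"], dat$G)
    rg <- genetic_correlation(dat$Y[, "A"], dat$Y[, "B"], dat$G)
    rows[[s]] <- data.frame(
      seed = s, h2_A = h2A$h2, h2_B = h2B$h2, rg = rg$r_G,
      true_h2_A = dat$truth$realized_h2[["A"]],
      true_h2_B = dat$truth$realized_h2[["B"]],
      true_rg = dat$truth$realized_genetic_corr[1, 2])
  }
  do.call(rbind, rows)
}

#' @rdname benchmark_parameter_recovery
#' @param replicates CV replicates per model.
#' @param models model tags to evaluate.
#' @param primary_h2 heritability of the primary trait (0 gives the
#'   pure-noise null calibration).
#' @param r_g genetic correlation between primary and secondary trait.
#' @export
benchmark_cv_advantage <- function(replicates = 50, seed = 1,
                                   models = c("unigs", "gs_sri", "multigs"),
                                   primary_h2 = 0.3, r_g = 0.7,
                                   n_markers = 2000) {
  gc2 <- matrix(c(1, r_g, r_g, 1), 2)
  if (primary_h2 == 0) gc2 <- diag(2)
  cfg <- sim_config(n_families = 30, lines_per_family = 20,
                    n_markers = n_markers,
                    trait_names = c("primary", "secondary"),
                    target_h2 = c(primary = primary_h2, secondary = 0.8),
                    genetic_corr = gc2,
                    residual_corr = matrix(c(1, .2, .2, 1), 2),
                    n_environments = 1, n_blocks = 12,
                    seed = derive_seed(seed, "cvbench"))
  dat <- simulate_blue_dataset(cfg)
  out <- list()
  for (mod in models)
    out[[mod]] <- kfold_cv(dat$Y[, "primary"], dat$G,
                           sri = dat$Y[, "secondary", drop = FALSE],
                           model = mod, replicates = replicates, seed = seed)
  out
}

#' @rdname benchmark_parameter_recovery
#' @param n_datasets independent null datasets to average over. A single
#'   dataset's null accuracy carries sd ~ 0.07 of family-structured
#'   kinship noise, so calibration is judged on the mean across datasets.
#' @export
benchmark_null_calibration <- function(n_datasets = 12, replicates = 6,
                                       seed = 1, n_markers = 2000) {
  means <- vapply(seq_len(n_datasets), function(s) {
    cv <- benchmark_cv_advantage(replicates = replicates,
                                 seed = derive_seed(seed, paste0("null", s)),
                                 models = "unigs", primary_h2 = 0,
                                 n_markers = n_markers)
    cv$unigs$mean
  }, numeric(1))
  list(dataset_means = means, mean = mean(means),
       se = stats::sd(means) / sqrt(n_datasets))
}

## simulate one environment, adjust plots to BLUEs, build the GRM;
## returns genotype-level BLUE matrix Y (RILs only), G, and the truth
simulate_blue_dataset <- function(cfg) {
  geno <- simulate_nam_genotypes(cfg)
  tr <- simulate_traits(geno, cfg)
  plots <- simulate_field_layout(tr$values, cfg)
  rils <- rownames(geno)[!attr(geno, "is_check")]
  Y <- sapply(cfg$trait_names, function(t2) {
    b <- fit_acbd_blue(plots, t2)
    b <- b[!b$is_check, ]
    stats::setNames(b$value, b$genotype_id)[rils]
  })
  G <- compute_grm(impute_missing(unclass(geno)[rils, , drop = FALSE]))
  list(Y = Y, G = G, truth = tr$truth, plots = plots, geno = geno)
}
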