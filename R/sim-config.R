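#' Configuration for the NAM-population simulator
#'
#' Bundles and validates every knob of the synthetic nested association
#' mapping (NAM) trial: population structure, genetic map, trait
#' architecture, and the augmented field layout. The defaults emulate the
#' study conditions of a spring-wheat NAM panel: half-sib families of
#' recombinant inbred lines (RILs) derived from one common parent, advanced
#' by five generations of selfing, grown in augmented complete block
#' designs where 15--20% of plots are replicated checks.
#'
#' @param n_families number of half-sib families (founder crosses).
#' @param lines_per_family RILs retained per family.
#' @param n_markers total biallelic markers, spread across chromosomes.
#' @param n_chromosomes number of chromosomes (21 for hexaploid wheat).
#' @param map_length_per_chrom genetic length of each chromosome, Morgans.
#' @param selfing_generations rounds of selfing after the F1 (default 5;
#'   expected residual heterozygosity is \eqn{0.5^g}).
#' @param trait_names character vector of trait labels. The first is taken
#'   as the primary trait by downstream benchmarks.
#' @param target_h2 named vector of narrow-sense heritabilities in [0,1],
#'   one per trait (genotype-level basis; see the methods vignette).
#' @param genetic_corr symmetric positive semi-definite correlation matrix
#'   of additive effects across traits (unit diagonal).
#' @param residual_corr symmetric PSD correlation matrix of residuals.
#' @param n_environments number of environments (years).
#' @param env_mean_sd sd of environment-level mean shifts (trait-sd units).
#' @param check_fraction fraction of plots sown to replicated checks
#'   (field practice 0.15--0.20).
#' @param n_checks number of replicated check genotypes (>= 2).
#' @param n_blocks blocks per environment.
#' @param block_sd sd of block effects (trait-sd units).
#' @param plot_error_sd sd of extra plot-level error added by the field
#'   layout on top of the genotype-level residual (default 0; see vignette).
#' @param founder_freq_range range of the uniform distribution founder
#'   allele frequencies are drawn from (degenerate ranges such as c(1, 1)
#'   give identical founders and a monomorphic population).
#' @param missing_rate per-cell marker missingness injected for QC testing.
#' @param low_maf_rate fraction of markers carried by a single founder only,
#'   yielding sub-threshold minor allele frequencies for QC testing.
#' @param seed integer root seed; all stages derive named substreams from it.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_families = 32, lines_per_family = 20,
                       n_markers = 2000, n_chromosomes = 21,
                       map_length_per_chrom = 1.5,
                       selfing_generations = 5,
                       trait_names = c("yield", "GPC"),
                       target_h2 = c(yield = 0.3, GPC = 0.6),
                       genetic_corr = NULL, residual_corr = NULL,
                       n_environments = 3, env_mean_sd = 0.5,
                       check_fraction = 0.16, n_checks = 3,
                       n_blocks = 10, block_sd = 0.5, plot_error_sd = 0,
                       founder_freq_range = c(0.1, 0.9),
                       missing_rate = 0, low_maf_rate = 0, seed = 1) {
  t <- length(trait_names)
  if (is.null(genetic_corr)) genetic_corr <- diag(t)
  if (is.null(residual_corr)) residual_corr <- diag(t)
  genetic_corr <- as.matrix(genetic_corr)
  residual_corr <- as.matrix(residual_corr)
  dimnames(genetic_corr) <- dimnames(residual_corr) <- list(trait_names, trait_names)

  if (anyDuplicated(trait_names))
    stop("trait_names must be unique")
  if (length(target_h2) != t)
    stop("target_h2 must have one entry per trait")
  if (is.null(names(target_h2))) names(target_h2) <- trait_names
  target_h2 <- target_h2[trait_names]
  if (any(!is.finite(target_h2)) || any(target_h2 < 0) || any(target_h2 > 1))
    stop("all target_h2 must lie in [0, 1]")
  for (nm in c("genetic_corr", "residual_corr")) {
    m <- get(nm)
    if (nrow(m) != t || ncol(m) != t)
      stop(nm, " must be ", t, "x", t)
    if (max(abs(diag(m) - 1)) > 1e-10)
      stop(nm, " must have unit diagonal")
    if (max(abs(m)) > 1 + 1e-10)
      stop(nm, " entries must lie in [-1, 1]")
    if (!is_psd(m))
      stop(nm, " must be symmetric positive semi-definite")
  }
  if (check_fraction < 0 || check_fraction >= 1)
    stop("check_fraction must lie in [0, 1)")
  if (n_checks < 2) stop("n_checks must be >= 2 (replication for H2)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (low_maf_rate < 0 || low_maf_rate >= 1) stop("low_maf_rate must lie in [0, 1)")
  if (length(founder_freq_range) != 2 || any(founder_freq_range < 0) ||
      any(founder_freq_range > 1) || founder_freq_range[1] > founder_freq_range[2])
    stop("founder_freq_range must be an increasing pair in [0, 1]")
  stopifnot(n_families >= 1, lines_per_family >= 1, n_markers >= 2,
            n_chromosomes >= 1, map_length_per_chrom > 0,
            selfing_generations >= 1, n_environments >= 1, n_blocks >= 1)

  structure(list(
    n_families = as.integer(n_families),
    lines_per_family = as.integer(lines_per_family),
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    map_length_per_chrom = map_length_per_chrom,
    selfing_generations = as.integer(selfing_generations),
    trait_names = trait_names, target_h2 = target_h2,
    genetic_corr = genetic_corr, residual_corr = residual_corr,
    n_environments = as.integer(n_environments), env_mean_sd = env_mean_sd,
    check_fraction = check_fraction, n_checks = as.integer(n_checks),
    n_blocks = as.integer(n_blocks), block_sd = block_sd,
    plot_error_sd = plot_error_sd, founder_freq_range = founder_freq_range,
    missing_rate = missing_rate, low_maf_rate = low_maf_rate,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("NAM simulation configuration\n")
  cat(sprintf("  population : %d families x %d RILs (+%d checks), %d selfing generations\n",
              x$n_families, x$lines_per_family, x$n_checks, x$selfing_generations))
  cat(sprintf("  genome     : %d markers on %d chromosomes of %.2f M\n",
              x$n_markers, x$n_chromosomes, x$map_length_per_chrom))
  cat(sprintf("  traits     : %s (h2: %s)\n", paste(x$trait_names, collapse = ", "),
              paste(sprintf("%.2f", x$target_h2), collapse = ", ")))
  cat(sprintf("  field      : %d environments, %d blocks, check fraction %.2f\n",
              x$n_environments, x$n_blocks, x$check_fraction))
  cat(sprintf("  seed       : %d\n", x$seed))
  invisible(x)
}
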