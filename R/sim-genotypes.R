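#' Simulate NAM genotypes by selfing with recombination
#'
#' Builds a nested association mapping population: one common inbred parent
#' crossed to \code{n_families} inbred founders, each F1 advanced by
#' \code{selfing_generations} rounds of selfing. Meiosis follows the
#' Haldane (no-interference) model: crossovers are Poisson along the map,
#' which at the marker loci is equivalent to independent inter-marker
#' recombination events with fraction \eqn{r = (1 - e^{-2d})/2} for
#' adjacent-marker distance \eqn{d} Morgans (and \eqn{r = 1/2} across
#' chromosome boundaries). Founder haplotypes are drawn per locus
#' i.i.d. Bernoulli with allele frequency ~ U(0.1, 0.9).
#'
#' The returned dosage matrix is oriented to the minor allele (codes 0/1/2
#' count copies of the minor allele among the RILs). The check genotypes
#' (common parent plus the first founders) are appended as fully inbred
#' lines. Missingness and single-founder (low-MAF) markers can be injected
#' for QC testing; when missingness is injected the complete matrix is
#' retained in attribute \code{"complete"}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return Integer matrix (lines x markers, NA = missing) with attributes
#'   \code{map} (data.frame marker/chrom/pos), \code{family},
#'   \code{is_check}, and (if missingness injected) \code{complete}.
#' @export
simulate_nam_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genotypes"))
  m <- config$n_markers
  nf <- config$n_families
  npl <- config$lines_per_family
  n <- nf * npl

  ## genetic map: markers spread evenly over chromosomes
  per_chrom <- diff(round(seq(0, m, length.out = config$n_chromosomes + 1L)))
  chrom <- rep(seq_len(config$n_chromosomes), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k)
    seq(0, config$map_length_per_chrom, length.out = max(k, 2L))[seq_len(k)]))
  map <- data.frame(marker = sprintf("M%05d", seq_len(m)), chrom = chrom, pos = pos)

  ## adjacent recombination fractions (Haldane); 0.5 across chromosomes
  d <- diff(pos)
  r <- (1 - exp(-2 * d)) / 2
  r[diff(chrom) != 0] <- 0.5

  ## founder haplotypes: inbred parents, per-locus Bernoulli(freq ~ U(.1,.9))
  p <- runif(m, config$founder_freq_range[1], config$founder_freq_range[2])
  common <- as.integer(runif(m) < p)
  founders <- matrix(as.integer(runif(nf * m) < rep(p, each = nf)), nf, m)
  if (config$low_maf_rate > 0) {
    rare <- which(runif(m) < config$low_maf_rate)
    if (length(rare)) {
      common[rare] <- 0L
      founders[, rare] <- 0L
      carrier <- sample.int(nf, length(rare), replace = TRUE)
      founders[cbind(carrier, rare)] <- 1L
    }
  }

  ## F1 per family, then selfing with recombination, vectorised across lines
  H1 <- matrix(rep(common, each = n), n, m)
  H2 <- founders[rep(seq_len(nf), each = npl), , drop = FALSE]
  for (g in seq_len(config$selfing_generations)) {
    A <- recombine_gametes(H1, H2, r)
    B <- recombine_gametes(H1, H2, r)
    H1 <- A
    H2 <- B
  }
  geno <- H1 + H2

  ## checks: common parent + first founders, fully inbred
  check_idx <- seq_len(min(config$n_checks - 1L, nf))
  checks <- rbind(2L * common,
                  2L * founders[check_idx, , drop = FALSE])
  check_names <- c("CHK_common", sprintf("CHK_founder%d", check_idx))

  geno <- rbind(geno, checks)
  line_names <- c(sprintf("F%02d_L%03d", rep(seq_len(nf), each = npl),
                          rep(seq_len(npl), nf)), check_names)
  dimnames(geno) <- list(line_names, map$marker)

  ## orient to minor allele among the RILs
  f <- colMeans(geno[seq_len(n), , drop = FALSE]) / 2
  flip <- f > 0.5
  geno[, flip] <- 2L - geno[, flip]

  family <- c(rep(sprintf("F%02d", seq_len(nf)), each = npl),
              rep("check", nrow(checks)))
  is_check <- c(rep(FALSE, n), rep(TRUE, nrow(checks)))

  complete <- NULL
  if (config$missing_rate > 0) {
    complete <- geno
    drop <- matrix(runif(length(geno)) < config$missing_rate,
                   nrow(geno), ncol(geno))
    geno[drop] <- NA_integer_
  }
  structure(geno, map = map, family = family, is_check = is_check,
            complete = complete, class = c("nam_geno", class(geno)))
}

## one meiosis for every line at once: H1/H2 are lines x markers haplotype
## matrices, r the vector of adjacent-marker recombination fractions
recombine_gametes <- function(H1, H2, r) {
  n <- nrow(H1); m <- ncol(H1)
  if (m == 1L) {
    phase <- rbinom(n, 1L, 0.5)
    return(H1 * (1 - phase) + H2 * phase)
  }
  S <- matrix(as.integer(runif(n * (m - 1L)) < rep(r, each = n)), n, m - 1L)
  phase <- (rbinom(n, 1L, 0.5) + cbind(0L, row_cumsum(S))) %% 2L
  H1 * (1L - phase) + H2 * phase
}

#' Residual heterozygosity of a simulated population
#'
#' Fraction of heterozygous calls (code 1) among cells of loci that
#' segregate within each family (i.e. loci heterozygous in that family's
#' F1). The Mendelian expectation after g rounds of selfing from a
#' heterozygous F1 locus is \eqn{0.5^g}.
#'
#' @param geno matrix from \code{\link{simulate_nam_genotypes}}.
#' @return numeric fraction.
#' @export
residual_heterozygosity <- function(geno) {
  g <- if (!is.null(attr(geno, "complete"))) attr(geno, "complete") else geno
  fam <- attr(geno, "family")
  chk <- attr(geno, "is_check") %||% rep(FALSE, nrow(g))
  if (is.null(fam)) fam <- rep("all", nrow(g))
  fam <- fam[!chk]
  g <- g[!chk, , drop = FALSE]
  het <- 0; tot <- 0
  for (f in unique(fam)) {
    sub <- g[fam == f, , drop = FALSE]
    seg <- which(col_var(sub) > 0)
    if (!length(seg)) next
    het <- het + sum(sub[, seg] == 1L, na.rm = TRUE)
    tot <- tot + sum(!is.na(sub[, seg]))
  }
  if (tot == 0) return(0)
  het / tot
}

## column variances, NA-tolerant
col_var <- function(m) {
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  cs <- colSums(m * m, na.rm = TRUE)
  out <- (cs - n * mu^2) / pmax(n - 1, 1)
  out[n < 2] <- 0
  out
}
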