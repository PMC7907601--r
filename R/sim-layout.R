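#' Checks per block of an augmented design
#'
#' Rounding rule: \code{round(check_fraction * plots_per_block)} with a
#' minimum of 2 (broad-sense heritability needs replication).
#'
#' @param check_fraction fraction of plots sown to checks.
#' @param entries_per_block unreplicated entries per block.
#' @return integer number of check plots per block.
#' @export
checks_per_block <- function(check_fraction, entries_per_block) {
  if (check_fraction < 0 || check_fraction >= 1)
    stop("check_fraction must lie in [0, 1)")
  c0 <- round(check_fraction * entries_per_block / (1 - check_fraction))
  ## fixed point of c = round(cf * (entries + c))
  for (i in 1:4) c0 <- round(check_fraction * (entries_per_block + c0))
  max(2L, as.integer(c0))
}

#' Lay out genotype values on an augmented complete block design
#'
#' Assigns the unreplicated entries of each environment to blocks (seeded
#' shuffle), replicates every check genotype once per block, and adds block
#' effects and plot error. Each unreplicated entry appears exactly once per
#' environment; checks appear in every block.
#'
#' @param genotype_values data.frame from \code{\link{simulate_traits}}
#'   (columns environment, genotype_id, is_check, then trait columns).
#' @param config a \code{\link{sim_config}}; uses \code{n_blocks},
#'   \code{check_fraction}, \code{block_sd}, \code{plot_error_sd}, and the
#'   "layout" substream of \code{seed}.
#' @return plot-level data.frame: environment, block, plot_id, genotype_id,
#'   is_check, one column per trait.
#' @export
simulate_field_layout <- function(genotype_values, config) {
  stopifnot(inherits(config, "sim_config"))
  need <- c("environment", "genotype_id", "is_check")
  if (!all(need %in% names(genotype_values)))
    stop("genotype_values must have columns ", paste(need, collapse = ", "))
  traits <- setdiff(names(genotype_values), need)
  set.seed(derive_seed(config$seed, "layout"))
  out <- list()
  for (env in unique(genotype_values$environment)) {
    sub <- genotype_values[genotype_values$environment == env, , drop = FALSE]
    entries <- sub[!sub$is_check, , drop = FALSE]
    checks <- sub[sub$is_check, , drop = FALSE]
    n_blocks <- min(config$n_blocks, nrow(entries))
    perm <- sample.int(nrow(entries))
    block_of <- rep(seq_len(n_blocks), length.out = nrow(entries))[order(perm)]
    epb <- ceiling(nrow(entries) / n_blocks)
    ncheck <- if (nrow(checks)) checks_per_block(config$check_fraction, epb) else 0L
    ## replicate check genotypes (cycled) to fill ncheck plots per block
    rows <- list()
    for (b in seq_len(n_blocks)) {
      e_b <- entries[block_of == b, , drop = FALSE]
      if (ncheck > 0) {
        c_b <- checks[rep(seq_len(nrow(checks)), length.out = ncheck), , drop = FALSE]
        e_b <- rbind(e_b, c_b)
      }
      e_b$block <- sprintf("B%02d", b)
      rows[[b]] <- e_b
    }
    plots <- do.call(rbind, rows)
    ## block effects and plot error, independent per trait
    for (tr in traits) {
      beff <- rnorm(n_blocks, 0, config$block_sd)
      names(beff) <- sprintf("B%02d", seq_len(n_blocks))
      plots[[tr]] <- plots[[tr]] + beff[plots$block] +
        rnorm(nrow(plots), 0, config$plot_error_sd)
    }
    plots$plot_id <- sprintf("%s_P%04d", env, seq_len(nrow(plots)))
    out[[env]] <- plots
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("environment", "block", "plot_id", "genotype_id", "is_check", traits)]
}
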