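#' Genotype-level BLUEs from an augmented complete block design
#'
#' Fixed-effects adjustment for the model
#' \deqn{Y_{ij} = \mu + Block_i + Check_j + e_{ij}}
#' fitted to the replicated check plots with sum-to-zero constraints on
#' blocks and check entries. Each unreplicated entry is adjusted by its
#' block's estimated deviation (classical augmented-design adjustment,
#' BLUE = observation - block deviation); check BLUEs are
#' \eqn{\hat\mu + \widehat{Check}_j}. Environments are fitted separately.
#'
#' @param plots plot-level data.frame with columns environment, block,
#'   genotype_id, is_check, and the trait column.
#' @param trait name of the trait column to adjust.
#' @return data.frame of class \code{blue_table}: environment,
#'   genotype_id, trait, value, is_check -- one row per genotype x
#'   environment.
#' @export
fit_acbd_blue <- function(plots, trait) {
  need <- c("environment", "block", "genotype_id", "is_check", trait)
  if (!all(need %in% names(plots)))
    stop("plots must have columns ", paste(need, collapse = ", "))
  out <- list()
  for (env in unique(plots$environment)) {
    sub <- plots[plots$environment == env, , drop = FALSE]
    y <- sub[[trait]]
    entries <- sub[!sub$is_check, , drop = FALSE]
    if (anyDuplicated(entries$genotype_id))
      stop("duplicated unreplicated entr", "y/ies in ", env, ": ",
           paste(unique(entries$genotype_id[duplicated(entries$genotype_id)]),
                 collapse = ", "))
    blocks <- unique(sub$block)
    has_check <- vapply(blocks, function(b)
      any(sub$is_check[sub$block == b]), logical(1))
    if (length(blocks) > 1 && !all(has_check))
      stop("block(s) without checks in ", env, ": ",
           paste(blocks[!has_check], collapse = ", "),
           " (block effect inestimable)")
    bdev <- stats::setNames(rep(0, length(blocks)), blocks)
    checks <- sub[sub$is_check, , drop = FALSE]
    if (length(blocks) > 1 && nrow(checks)) {
      cd <- data.frame(y = checks[[trait]],
                       blockF = factor(checks$block, levels = blocks),
                       checkF = factor(checks$genotype_id))
      fit <- stats::lm(y ~ blockF + checkF, data = cd,
                       contrasts = list(blockF = "contr.sum",
                                        checkF = "contr.sum"))
      cf <- stats::coef(fit)
      nb <- length(blocks)
      bmain <- cf[grep("^blockF", names(cf))]
      if (anyNA(bmain)) stop("block effects inestimable in ", env,
                             " (checks not connected across blocks)")
      bdev[] <- c(bmain, -sum(bmain))
      mu <- cf[["(Intercept)"]]
      ck_levels <- levels(cd$checkF)
      cmain <- cf[grep("^checkF", names(cf))]
      ceff <- stats::setNames(c(cmain, -sum(cmain)), ck_levels)
      check_blue <- mu + ceff
    } else if (nrow(checks)) {
      check_blue <- tapply(checks[[trait]], checks$genotype_id, mean)
    } else {
      check_blue <- numeric(0)
    }
    entry_blue <- entries[[trait]] - bdev[entries$block]
    res <- rbind(
      data.frame(environment = env, genotype_id = entries$genotype_id,
                 trait = trait, value = unname(entry_blue), is_check = FALSE),
      if (length(check_blue))
        data.frame(environment = env, genotype_id = names(check_blue),
                   trait = trait, value = unname(check_blue), is_check = TRUE))
    out[[env]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("blue_table", class(res))
  res
}

#' Broad-sense heritability from replicated plots
#'
#' One-random-effect REML on the plot data of one environment (genotype
#' random, mean and block fixed):
#' \eqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)} on a plot basis,
#' clamped to [0, 1]. Solved with the package's profiled spectral REML
#' using the genotype-incidence kinship \eqn{ZZ'}; replication (checks
#' across blocks, or any repeated genotype) is required to separate
#' \eqn{\sigma^2_g} from \eqn{\sigma^2_e}.
#'
#' @param plots plot-level data.frame (one environment, or use
#'   \code{environment} to pick one): columns block, genotype_id, trait.
#' @param trait trait column name.
#' @param environment optional environment label to subset on.
#' @return list of class \code{genetic_params}: H2, sigma2_g, sigma2_e.
#' @export
broad_sense_h2 <- function(plots, trait, environment = NULL) {
  if (!is.null(environment))
    plots <- plots[plots$environment == environment, , drop = FALSE]
  if (!is.null(plots$environment) && length(unique(plots$environment)) > 1)
    stop("broad_sense_h2 is fitted per environment; pass one environment")
  y <- plots[[trait]]
  gf <- factor(plots$genotype_id)
  if (!any(duplicated(plots$genotype_id)))
    stop("no replicated genotypes; sigma2_g and sigma2_e are not separable")
  Z <- outer(as.character(gf), levels(gf), `==`) * 1
  K <- tcrossprod(Z)
  bf <- factor(plots$block)
  X <- if (nlevels(bf) > 1) stats::model.matrix(~bf) else matrix(1, length(y), 1)
  fit <- reml_single_trait(y, K, X = X)
  H2 <- max(0, min(1, fit$sigma2_a / (fit$sigma2_a + fit$sigma2_e)))
  structure(list(H2 = H2, sigma2_g = fit$sigma2_a, sigma2_e = fit$sigma2_e,
                 boundary = fit$boundary, fit = fit),
            class = "genetic_params")
}
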