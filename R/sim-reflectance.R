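#' Simulate 16-band canopy reflectance carrying latent index targets
#'
#' Parametric canopy model: a baseline log-reflectance spectrum at the 16
#' radiometer bands is perturbed along three latent axes -- greenness
#' (driven by the NDVI target), water status (NWI target) and pigment
#' composition (PRI target) -- mapped log-linearly to the bands, plus a
#' small band-wise noise. The loadings are calibrated so the indices
#' recomputed from the emitted spectra by \code{\link{compute_indices}}
#' correlate strongly (> 0.9) with the latent targets. All reflectances
#' lie strictly in (0, 1).
#'
#' Exact inversion of all eight index formulas is over-determined (the
#' indices share bands), so generation is latent-axis based: targets for
#' indices other than the three drivers emerge through the shared bands.
#'
#' @param sri_values data.frame with id columns (plot_id and/or
#'   genotype_id, environment, stage) and latent target columns among
#'   NDVI, NWI, PRI (missing axes default to zero variation).
#' @param config a \code{\link{sim_config}} (seed substream "reflectance").
#' @param noise_sd sd of band-wise log-reflectance noise.
#' @return data.frame: id columns plus R430 ... R970 columns.
#' @export
simulate_reflectance <- function(sri_values, config, noise_sd = 0.02) {
  stopifnot(inherits(config, "sim_config"))
  wl <- default_band_wavelengths()
  req <- required_wavelengths()
  miss <- req[vapply(req, function(b) min(abs(wl - b)) > 15, logical(1))]
  if (length(miss))
    stop("band map lacks wavelengths required by the indices: ",
         paste(miss, collapse = ", "))
  ids <- intersect(c("plot_id", "genotype_id", "environment", "stage"),
                   names(sri_values))
  n <- nrow(sri_values)

  ## baseline healthy-canopy spectrum (fractional reflectance)
  base <- c(`430` = 0.040, `450` = 0.045, `490` = 0.050, `531` = 0.060,
            `550` = 0.080, `570` = 0.070, `610` = 0.055, `650` = 0.045,
            `680` = 0.040, `700` = 0.100, `720` = 0.250, `780` = 0.450,
            `800` = 0.470, `880` = 0.460, `900` = 0.450, `970` = 0.350)
  ## log-linear loadings of the three latent axes on the bands
  L <- matrix(0, length(wl), 3, dimnames = list(names(base),
                                                c("green", "water", "pigment")))
  L[c("610", "650", "680", "700"), "green"] <- c(-0.15, -0.35, -0.45, -0.25)
  L[c("780", "800", "880", "900"), "green"] <- 0.10
  L["970", "water"] <- 0.35
  L[c("531", "570", "430", "550"), "pigment"] <- c(0.18, -0.18, -0.10, -0.05)

  z <- matrix(0, n, 3)
  axes <- c(green = "NDVI", water = "NWI", pigment = "PRI")
  for (k in seq_along(axes)) {
    tgt <- sri_values[[axes[k]]]
    if (!is.null(tgt) && stats::sd(tgt) > 0) z[, k] <- as.numeric(scale(tgt))
  }

  set.seed(derive_seed(config$seed, "reflectance"))
  logR <- matrix(rep(log(base), each = n), n, length(wl)) +
    tcrossprod(z, L) + matrix(rnorm(n * length(wl), 0, noise_sd), n)
  R <- pmin(pmax(exp(logR), 1e-4), 0.999)
  out <- sri_values[, ids, drop = FALSE]
  for (j in seq_along(wl)) out[[paste0("R", wl[j])]] <- R[, j]
  rownames(out) <- NULL
  out
}
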