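#' Spectral reflectance index definitions
#'
#' The eight canopy indices, each a function of reflectance at named
#' wavelengths (nm):
#' \itemize{
#'   \item NDVI  = (R800 - R680) / (R800 + R680)
#'   \item NWI   = (R970 - R880) / (R970 + R880)
#'   \item WI    = R970 / R900
#'   \item SR    = R800 / R680
#'   \item GNDVI = (R780 - R550) / (R780 + R550)
#'   \item PRI   = (R531 - R570) / (R531 + R570)
#'   \item NCPI  = (R680 - R430) / (R680 + R430)
#'   \item ARI   = R800 (1/R550 - 1/R700)
#' }
#'
#' @return named list; each element has \code{bands} (wavelengths used) and
#'   \code{fun} (function of a named reflectance list).
#' @export
sri_definitions <- function() {
  list(
    NDVI  = list(bands = c(800, 680),
                 fun = function(R) (R$`800` - R$`680`) / (R$`800` + R$`680`)),
    NWI   = list(bands = c(970, 880),
                 fun = function(R) (R$`970` - R$`880`) / (R$`970` + R$`880`)),
    WI    = list(bands = c(970, 900),
                 fun = function(R) R$`970` / R$`900`),
    SR    = list(bands = c(800, 680),
                 fun = function(R) R$`800` / R$`680`),
    GNDVI = list(bands = c(780, 550),
                 fun = function(R) (R$`780` - R$`550`) / (R$`780` + R$`550`)),
    PRI   = list(bands = c(531, 570),
                 fun = function(R) (R$`531` - R$`570`) / (R$`531` + R$`570`)),
    NCPI  = list(bands = c(680, 430),
                 fun = function(R) (R$`680` - R$`430`) / (R$`680` + R$`430`)),
    ARI   = list(bands = c(800, 550, 700),
                 fun = function(R) R$`800` * (1 / R$`550` - 1 / R$`700`))
  )
}

## wavelengths (nm) of the simulated 16-band radiometer
#' @rdname sri_definitions
#' @export
default_band_wavelengths <- function() {
  c(430, 450, 490, 531, 550, 570, 610, 650, 680, 700, 720, 780, 800, 880, 900, 970)
}

## wavelengths any index may request
required_wavelengths <- function() {
  sort(unique(unlist(lapply(sri_definitions(), `[[`, "bands"))))
}

## columns named R<nm> -> available wavelengths
panel_wavelengths <- function(panel) {
  nm <- grep("^R[0-9]+$", names(panel), value = TRUE)
  if (!length(nm)) stop("no reflectance columns of the form R<nm> found")
  stats::setNames(as.numeric(sub("^R", "", nm)), nm)
}

#' Average repeated reflectance scans to one record per plot and stage
#'
#' Arithmetic mean of every band over the scans of a plot at a growth
#' stage; averaging precedes index computation (index of the mean spectrum,
#' not mean of per-scan indices). Plots listed in \code{expected_plots}
#' but absent from the scans are reported in the \code{"excluded"}
#' attribute rather than silently dropped.
#'
#' @param raw_scans data.frame with columns plot_id, and optionally
#'   genotype_id, environment, stage, plus reflectance columns R<nm>; one
#'   row per scan.
#' @param expected_plots optional character vector of plot ids that should
#'   be present.
#' @return data.frame with one row per plot x stage; attribute
#'   \code{excluded} lists expected plots with zero scans.
#' @export
average_plot_reflectance <- function(raw_scans, expected_plots = NULL) {
  wl <- panel_wavelengths(raw_scans)
  bands <- names(wl)
  if (anyNA(raw_scans[bands]))
    stop("scans with mismatched band sets (missing reflectance values)")
  keys <- intersect(c("plot_id", "genotype_id", "environment", "stage"),
                    names(raw_scans))
  if (!"plot_id" %in% keys) stop("raw_scans must have a plot_id column")
  grp <- interaction(raw_scans[intersect(c("plot_id", "stage"), keys)],
                     drop = TRUE, lex.order = TRUE)
  first <- !duplicated(grp)
  out <- raw_scans[first, keys, drop = FALSE]
  for (b in bands)
    out[[b]] <- as.numeric(tapply(raw_scans[[b]], grp, mean)[as.character(grp[first])])
  rownames(out) <- NULL
  excluded <- setdiff(expected_plots %||% character(), raw_scans$plot_id)
  attr(out, "excluded") <- excluded
  out
}

#' Compute the eight spectral reflectance indices
#'
#' Each index wavelength is matched to the nearest available band within
#' \code{max_band_distance} nm (an error names the index and wavelength
#' when no band is close enough). Any index whose denominator band is
#' <= \code{guard} is set missing rather than infinite; such records are
#' counted in the \code{"guarded"} attribute.
#'
#' @param panel data.frame with reflectance columns R<nm> and any id
#'   columns (plot_id, genotype_id, environment, stage), e.g. the output of
#'   \code{\link{average_plot_reflectance}}.
#' @param max_band_distance maximum nm between an index wavelength and the
#'   band used for it (default 15).
#' @param guard denominators at or below this are treated as missing.
#' @return data.frame: the id columns followed by NDVI, NWI, WI, SR,
#'   GNDVI, PRI, NCPI, ARI.
#' @export
compute_indices <- function(panel, max_band_distance = 15, guard = 1e-9) {
  wl <- panel_wavelengths(panel)
  defs <- sri_definitions()
  ## resolve every required wavelength to the nearest available band
  resolve <- list()
  for (ix in names(defs)) {
    for (b in defs[[ix]]$bands) {
      d <- abs(wl - b)
      j <- which.min(d)
      if (d[j] > max_band_distance)
        stop(sprintf("index %s needs a band near %d nm; nearest available is %g nm away",
                     ix, b, d[j]))
      resolve[[as.character(b)]] <- names(wl)[j]
    }
  }
  ids <- intersect(c("plot_id", "genotype_id", "environment", "stage"), names(panel))
  out <- panel[, ids, drop = FALSE]
  guarded <- 0L
  for (ix in names(defs)) {
    R <- lapply(defs[[ix]]$bands, function(b) panel[[resolve[[as.character(b)]]]])
    names(R) <- as.character(defs[[ix]]$bands)
    val <- defs[[ix]]$fun(R)
    ## guard: indices are ratios; tiny bands anywhere in the formula are suspect
    bad <- Reduce(`|`, lapply(R, function(v) v <= guard))
    if (any(bad)) {
      val[bad] <- NA_real_
      guarded <- guarded + sum(bad)
    }
    out[[ix]] <- val
  }
  attr(out, "guarded") <- guarded
  rownames(out) <- NULL
  out
}
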