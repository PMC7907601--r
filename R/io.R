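#' Read a genotype matrix
#'
#' CSV layout: first column \code{line_id}, remaining columns one marker
#' each, cells in {0, 1, 2, NA} (minor-allele dosage). VCF import (via
#' the vcfR package) keeps biallelic SNPs only -- other records are
#' skipped with a warning -- and orients GT codes to the minor allele.
#'
#' @param path file path.
#' @param format "csv" or "vcf".
#' @return numeric matrix, lines x markers, with dimnames.
#' @export
read_genotypes <- function(path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "line_id")
      stop("genotype CSV must have line_id as its first column")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$line_id
    storage.mode(m) <- "numeric"
    bad <- which(!is.na(m) & !(m %in% c(0, 1, 2)), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("invalid genotype code %s at line '%s', marker '%s'",
                   m[bad[1, , drop = FALSE]], rownames(m)[bad[1, 1]],
                   colnames(m)[bad[1, 2]]))
    return(m)
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- vcfR::is.biallelic(v)
  if (any(!biallelic))
    warning(sum(!biallelic), " non-biallelic record(s) skipped")
  v <- v[biallelic, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
  })
  m <- t(dose)
  ## orient to the minor allele
  f <- colMeans(m, na.rm = TRUE) / 2
  m[, which(f > 0.5)] <- 2 - m[, which(f > 0.5), drop = FALSE]
  m
}

#' @rdname read_genotypes
#' @param m genotype matrix, lines x markers.
#' @export
write_genotypes <- function(m, path) {
  df <- data.frame(line_id = rownames(m) %||% seq_len(nrow(m)),
                   m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write plot-level phenotypes
#'
#' CSV with columns environment, block, plot_id, genotype_id, is_check and
#' one column per trait.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("is_check" %in% names(df)) df$is_check <- as.logical(df$is_check)
  df
}

#' @rdname read_phenotypes
#' @param df plot table.
#' @export
write_phenotypes <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reflectance panel
#'
#' Columns: plot_id, genotype_id, environment, stage, then one column per
#' band named R<nm>. Radiometers report either percent or fractional
#' reflectance; values are normalised to fractions when the maximum
#' exceeds 1.5.
#'
#' @param path file path.
#' @return data.frame with fractional reflectances.
#' @export
read_reflectance <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wl <- panel_wavelengths(df)
  bands <- names(wl)
  mx <- max(as.matrix(df[bands]), na.rm = TRUE)
  if (mx > 1.5) {
    df[bands] <- df[bands] / 100
    message("reflectance read as percent; normalised to fractions")
  }
  df
}

#' @rdname read_reflectance
#' @param df reflectance table.
#' @export
write_reflectance <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
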