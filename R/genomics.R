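#' Marker quality control
#'
#' Filter order follows standard practice for these panels: lines with too
#' much missing genotype data are removed first, then markers with too much
#' missingness, then markers with low minor allele frequency (computed
#' after the missingness filters). Because removing markers changes the
#' line-wise missing fractions (and vice versa), the two missingness
#' filters are iterated in that order until nothing more is removed, so
#' filtering is idempotent. The MAF boundary keeps markers with
#' MAF >= \code{min_maf} and discards those below it.
#'
#' @param m numeric matrix, lines x markers, codes {0, 1, 2, NA}.
#' @param max_marker_missing markers missing in more than this fraction of
#'   lines are discarded (default 0.20).
#' @param max_line_missing lines missing more than this fraction of
#'   markers are discarded (default 0.10).
#' @param min_maf minimum minor allele frequency retained (default 0.10).
#' @return filtered matrix with attribute \code{qc_report}: a data.frame of
#'   counts removed at each step.
#' @export
qc_filter <- function(m, max_marker_missing = 0.20, max_line_missing = 0.10,
                      min_maf = 0.10) {
  stopifnot(is.matrix(m),
            max_marker_missing >= 0, max_marker_missing <= 1,
            max_line_missing >= 0, max_line_missing <= 1,
            min_maf >= 0, min_maf <= 1)
  check_codes(m)
  eps <- 1e-12
  steps <- list(lines_missing = 0L, markers_missing = 0L, markers_maf = 0L)

  repeat {
    keep_l <- rowMeans(is.na(m)) <= max_line_missing + eps
    steps$lines_missing <- steps$lines_missing + sum(!keep_l)
    m <- m[keep_l, , drop = FALSE]
    if (nrow(m) == 0) stop("line missingness filter removed every line")

    keep_m <- colMeans(is.na(m)) <= max_marker_missing + eps
    steps$markers_missing <- steps$markers_missing + sum(!keep_m)
    m <- m[, keep_m, drop = FALSE]
    if (ncol(m) == 0) stop("marker missingness filter removed every marker")

    f <- colMeans(m, na.rm = TRUE) / 2
    keep_f <- pmin(f, 1 - f) >= min_maf - eps
    steps$markers_maf <- steps$markers_maf + sum(!keep_f)
    m <- m[, keep_f, drop = FALSE]
    if (ncol(m) == 0) stop("MAF filter removed every marker")
    if (all(keep_l) && all(keep_m) && all(keep_f)) break
  }

  report <- data.frame(step = c("lines_missing", "markers_missing", "markers_maf"),
                       removed = unlist(steps),
                       threshold = c(max_line_missing, max_marker_missing, min_maf),
                       row.names = NULL)
  attr(m, "qc_report") <- report
  m
}

## genotype codes must be 0/1/2 (or imputed fractions in [0,2]) or NA
check_codes <- function(m, integer_only = FALSE) {
  v <- m[!is.na(m)]
  if (any(v < 0 | v > 2))
    stop("genotype codes outside [0, 2] found")
  if (integer_only && any(v != round(v)))
    stop("non-integer genotype codes found")
  invisible(TRUE)
}

#' Impute missing genotype codes by the per-marker mean
#'
#' @param m numeric matrix, lines x markers, codes {0, 1, 2, NA}.
#' @return matrix with no missing values (non-integer codes allowed).
#' @export
impute_missing <- function(m) {
  stopifnot(is.matrix(m))
  if (!anyNA(m)) return(m)
  nobs <- colSums(!is.na(m))
  if (any(nobs == 0))
    stop("cannot impute marker(s) with no observed genotypes: ",
         paste(utils::head(colnames(m)[nobs == 0] %||% which(nobs == 0), 5),
               collapse = ", "))
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- unname(mu[idx[, 2]])
  m
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \eqn{G = W W' / (2 \sum \hat p_j (1 - \hat p_j))} with W the dosage
#' matrix column-centred by \eqn{2\hat p_j}. Eigenvalues below
#' \code{floor} are clipped up to it so the matrix is safely positive
#' definite for downstream REML; whether clipping occurred is recorded in
#' the \code{conditioning} attribute.
#'
#' @param m numeric matrix, lines x markers, no missing codes (impute
#'   first).
#' @param floor eigenvalue floor for PSD conditioning.
#' @return symmetric n x n matrix with attributes \code{denom}
#'   (\eqn{2\sum p q}, the marker-to-line variance scale) and
#'   \code{conditioning}.
#' @export
compute_grm <- function(m, floor = 1e-8) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("missing genotype codes; impute before computing the GRM")
  p <- colMeans(m) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers are monomorphic; GRM denominator is zero")
  W <- sweep(m, 2, 2 * p)
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  clipped <- sum(e$values < floor)
  if (clipped > 0) {
    G <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
    G <- (G + t(G)) / 2
    dimnames(G) <- list(rownames(m), rownames(m))
  }
  attr(G, "denom") <- denom
  attr(G, "conditioning") <- list(floor = floor, clipped = clipped)
  G
}
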