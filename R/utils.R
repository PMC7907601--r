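#' Derive a named substream seed from a root seed
#'
#' All stochastic stages draw their randomness from one root seed through
#' named substreams, so each stage is independently reproducible.
#'
#' @param seed integer root seed.
#' @param stream character substream name (e.g. "genotypes", "effects").
#' @return An integer seed below 2^31, deterministic in (seed, stream).
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  v <- utf8ToInt(stream)
  h <- sum(v * seq_along(v)) %% 104729
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 12345) %% 2147483629)
}

## symmetric PSD check used by config validation
is_psd <- function(m, tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}

## clip eigenvalues of a symmetric matrix from below
psd_clip <- function(m, floor = 1e-8) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) >= floor) return(list(mat = m, clipped = FALSE))
  v <- pmax(e$values, floor)
  list(mat = e$vectors %*% (v * t(e$vectors)), clipped = TRUE)
}

## row-wise cumulative sum by in-place column accumulation (fast for wide matrices)
row_cumsum <- function(m) {
  if (ncol(m) < 2L) return(m)
  for (j in 2:ncol(m)) m[, j] <- m[, j] + m[, j - 1L]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
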