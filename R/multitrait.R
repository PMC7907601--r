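#' Multi-trait GBLUP with unstructured covariances by EM-REML
#'
#' Fits the multi-trait genomic model
#' \deqn{y_{j} = \mu_j + g_j + e_j, \quad g \sim N(0, H \otimes G), \quad
#'       e \sim N(0, R \otimes I)}
#' with unstructured t x t genetic (H) and residual (R) covariance
#' matrices. Variance components are estimated by EM-REML on the lines
#' with complete records: the fixed trait means are projected out with an
#' orthonormal contrast basis, the projected relationship matrix is
#' eigendecomposed once, and each EM iteration simultaneously
#' diagonalises (H, R) so the E-step is a vectorised O(n t^2) pass.
#' H and R are projected to the PSD cone (eigenvalue floor) every step.
#'
#' Genetic values for all lines and traits are then obtained as the BLUP
#' from the multi-trait system including partially observed records: a
#' line whose primary trait is unrecorded still contributes its observed
#' secondary traits, which is how secondary-trait information transfers to
#' the primary GEBV. Rows are dropped per missing observation (unequal
#' design), never imputed.
#'
#' @param Y numeric matrix, lines x traits, NA = unobserved.
#' @param K genomic relationship matrix over all lines in Y.
#' @param tol EM stops when the relative restricted log-likelihood change
#'   falls below this (default 1e-6).
#' @param max_iter iteration cap (default 500); reaching it returns the
#'   last iterate with \code{converged = FALSE} and a warning.
#' @param psd_floor eigenvalue floor for the PSD projection of H and R.
#' @param min_obs minimum lines observed per trait (default 30).
#' @return object of class \code{gs_mtfit}: \code{H}, \code{R}, trait
#'   means \code{mu}, genetic correlations \code{rg} (clamped to [-1, 1]
#'   with \code{rg_boundary} flags), GEBV matrix \code{gebv} (lines x
#'   traits, centred), \code{loglik_trace}, \code{converged},
#'   \code{iterations}.
#' @export
fit_multitrait_gs <- function(Y, K, tol = 1e-6, max_iter = 500,
                              psd_floor = 1e-8, min_obs = 30) {
  Y <- as.matrix(Y)
  n <- nrow(Y); t <- ncol(Y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(t))
  nobs <- colSums(!is.na(Y))
  if (any(nobs < min_obs))
    stop("each trait must be observed on at least ", min_obs, " lines; short: ",
         paste(colnames(Y)[nobs < min_obs], collapse = ", "))
  zv <- apply(Y, 2, function(v) stats::var(v[!is.na(v)]) == 0)
  if (any(zv))
    stop("trait(s) with zero variance: ", paste(colnames(Y)[zv], collapse = ", "))

  complete <- which(stats::complete.cases(Y))
  m_c <- length(complete)
  if (m_c < min_obs)
    stop("need at least ", min_obs, " lines with complete records for EM-REML")
  Yc <- Y[complete, , drop = FALSE]
  Kc <- K[complete, complete, drop = FALSE]

  ## project out the per-trait means with an orthonormal contrast basis
  Qfull <- qr.Q(qr(matrix(1, m_c, 1)), complete = TRUE)
  Kb <- Qfull[, -1, drop = FALSE]
  A <- crossprod(Kb, Kc %*% Kb)
  eA <- eigen((A + t(A)) / 2, symmetric = TRUE)
  d <- pmax(eA$values, 0)
  Tm <- crossprod(eA$vectors, crossprod(Kb, Yc))   # m x t, rows independent
  m <- nrow(Tm)
  pos <- d > 1e-10
  m_H <- sum(pos)

  ## EM-REML with per-iteration simultaneous diagonalisation of (H, R)
  S <- crossprod(Tm) / m
  H <- S / (2 * max(mean(d), 1e-8))
  R <- S / 2
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    H <- psd_clip(H, psd_floor)$mat
    R <- psd_clip(R, psd_floor)$mat
    Ur <- chol(R)
    Wm <- backsolve(Ur, t(backsolve(Ur, H, transpose = TRUE)), transpose = TRUE)
    eW <- eigen((Wm + t(Wm)) / 2, symmetric = TRUE)
    lam <- pmax(eW$values, 0)
    Q <- backsolve(Ur, eW$vectors)          # Q' R Q = I, Q' H Q = diag(lam)
    Qinv <- crossprod(eW$vectors, Ur)
    U <- Tm %*% Q
    DL <- outer(d, lam)                     # m x t matrix of d_i * lambda_j
    ll <- -0.5 * (m * t * log(2 * pi) + m * 2 * sum(log(diag(Ur))) +
                    sum(log1p(DL)) + sum(U^2 / (1 + DL)))
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
    Mf <- DL / (1 + DL)
    V <- Mf * U
    W <- U - V
    sa <- lam * colSums(1 / (1 + DL[pos, , drop = FALSE]))
    se <- colSums(Mf)
    Vs <- V[pos, , drop = FALSE] / sqrt(d[pos])
    H <- crossprod(Qinv, (crossprod(Vs) + diag(sa, t)) %*% Qinv) / max(m_H, 1)
    R <- crossprod(Qinv, (crossprod(W) + diag(se, t)) %*% Qinv) / m
  }
  if (!converged)
    warning("EM-REML hit the iteration cap (", max_iter,
            "); returning the last iterate")
  H <- (H + t(H)) / 2; R <- (R + t(R)) / 2
  dimnames(H) <- dimnames(R) <- list(colnames(Y), colnames(Y))

  ## genetic correlations, clamped at the boundary with a flag
  sdH <- sqrt(pmax(diag(H), psd_floor))
  rg <- H / tcrossprod(sdH)
  rg_boundary <- abs(rg) > 1 - 1e-6
  rg <- pmin(pmax(rg, -1), 1)
  diag(rg) <- 1; diag(rg_boundary) <- FALSE

  ## conditional BLUP over all observed cells (partial records included)
  obs <- which(!is.na(Y), arr.ind = TRUE)
  l_idx <- obs[, 1]; j_idx <- obs[, 2]
  y_o <- Y[obs]
  Vo <- H[j_idx, j_idx] * K[l_idx, l_idx] +
    R[j_idx, j_idx] * outer(l_idx, l_idx, "==")
  Xo <- matrix(0, length(y_o), t)
  Xo[cbind(seq_along(y_o), j_idx)] <- 1
  sol <- solve(Vo, cbind(Xo, y_o))
  XtVi <- t(sol[, seq_len(t), drop = FALSE])
  mu <- drop(solve(XtVi %*% Xo, XtVi %*% y_o))
  Mv <- drop(sol[, t + 1] - sol[, seq_len(t), drop = FALSE] %*% mu)
  gebv <- matrix(0, n, t, dimnames = list(rownames(Y), colnames(Y)))
  for (k in seq_len(t))
    gebv[, k] <- K[, l_idx, drop = FALSE] %*% (Mv * H[k, j_idx])

  structure(list(H = H, R = R, mu = stats::setNames(mu, colnames(Y)),
                 rg = rg, rg_boundary = rg_boundary, gebv = gebv,
                 loglik_trace = trace, loglik = trace[length(trace)],
                 converged = converged, iterations = iter,
                 complete = complete, n = n, t = t),
            class = "gs_mtfit")
}

#' @export
print.gs_mtfit <- function(x, ...) {
  cat(sprintf("Multi-trait GBLUP (EM-REML), %d traits, %d lines (%d complete)\n",
              x$t, x$n, length(x$complete)))
  cat(sprintf("  restricted logLik %.4f after %d iterations%s\n", x$loglik,
              x$iterations, if (x$converged) "" else "  [not converged]"))
  cat("  genetic covariance H:\n")
  print(round(x$H, 4))
  cat("  residual covariance R:\n")
  print(round(x$R, 4))
  if (x$t > 1) {
    cat("  genetic correlations:\n")
    print(round(x$rg, 3))
    if (any(x$rg_boundary)) cat("  (boundary correlation flagged)\n")
  }
  invisible(x)
}
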