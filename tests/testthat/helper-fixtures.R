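## shared fixtures, all built in code

## small NAM config for fast tests
tiny_config <- function(..., seed = 11) {
  sim_config(n_families = 8, lines_per_family = 10, n_markers = 300,
             n_chromosomes = 5, n_environments = 1, n_blocks = 4,
             seed = seed, ...)
}

## dense random kinship: GRM of random biallelic markers
random_grm <- function(n, m = 400, seed = 1, p = 0.3) {
  set.seed(seed)
  M <- matrix(rbinom(n * m, 2, p), n, m)
  rownames(M) <- sprintf("L%03d", seq_len(n))
  compute_grm(M)
}

## draw y with a given h2 on a given kinship (genomic-heritability scale)
simulate_gblup_trait <- function(K, h2, seed = 1) {
  set.seed(seed)
  n <- nrow(K)
  e <- eigen(K, symmetric = TRUE)
  g <- e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(n))
  kbar <- mean(diag(K))
  sigma2_a <- h2 / kbar
  sigma2_e <- 1 - h2
  y <- drop(g) * sqrt(sigma2_a) + rnorm(n, 0, sqrt(max(sigma2_e, 0)))
  list(y = y, g = drop(g) * sqrt(sigma2_a),
       sigma2_a = sigma2_a, sigma2_e = sigma2_e)
}

## draw a bivariate trait matrix with genetic covariance H and residual R
simulate_bivariate <- function(K, H, R, seed = 1) {
  set.seed(seed)
  n <- nrow(K)
  e <- eigen(K, symmetric = TRUE)
  Kh <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  G <- Kh %*% matrix(rnorm(n * 2), n) %*% chol(H)
  E <- matrix(rnorm(n * 2), n) %*% chol(R + diag(1e-12, 2))
  list(Y = G + E, G = G)
}

## dense GLS/BLUP oracle for the univariate genomic model at fixed
## variance components: direct inversion of V = s2a K + s2e I
dense_gblup_oracle <- function(y, K, X, s2a, s2e) {
  V <- s2a * K + s2e * diag(length(y))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  g <- s2a * K %*% Vi %*% (y - X %*% beta)
  list(beta = drop(beta), g = drop(g))
}

## dense multi-trait BLUP oracle at fixed (H, R): full V over observed
## cells via kronecker products, trait-major ordering
dense_mt_oracle <- function(Y, K, H, R) {
  n <- nrow(Y); t <- ncol(Y)
  obs <- which(!is.na(Y))           # column-major == trait-major vec(Y)
  V <- (kronecker(H, K) + kronecker(R, diag(n)))[obs, obs]
  X <- kronecker(diag(t), matrix(1, n, 1))[obs, , drop = FALSE]
  y <- as.vector(Y)[obs]
  Vi <- solve(V)
  mu <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  w <- Vi %*% (y - X %*% mu)
  g <- kronecker(H, K)[, obs] %*% w
  list(mu = drop(mu), gebv = matrix(g, n, t))
}

## dense restricted log-likelihood of the multi-trait model (complete
## data): projects out the trait means with an orthonormal contrast basis
dense_mt_loglik <- function(Y, K, H, R) {
  n <- nrow(Y); t <- ncol(Y)
  Kb <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  P <- kronecker(diag(t), t(Kb))
  Vp <- P %*% (kronecker(H, K) + kronecker(R, diag(n))) %*% t(P)
  r <- P %*% as.vector(Y)
  m <- nrow(Vp)
  -0.5 * (m * log(2 * pi) + determinant(Vp)$modulus[1] +
            drop(t(r) %*% solve(Vp, r)))
}
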