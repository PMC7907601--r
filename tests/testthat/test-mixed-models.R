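test_that("profiled REML beats a 1000-point grid oracle", {
  K <- random_grm(120, seed = 2)
  sim <- simulate_gblup_trait(K, 0.5, seed = 3)
  fit <- reml_single_trait(sim$y, K)
  grid <- exp(seq(-10, 10, length.out = 1000))
  expect_gte(fit$loglik, max(reml_loglik(grid, sim$y, K)) - 1e-6)
  ## with covariates too
  set.seed(4)
  X <- cbind(1, rnorm(120))
  fitX <- reml_single_trait(sim$y + X[, 2], K, X = X)
  expect_gte(fitX$loglik, max(reml_loglik(grid, sim$y + X[, 2], K, X = X)) - 1e-6)
})

test_that("pure noise against an I-like kinship lands on the zero-variance boundary", {
  K <- random_grm(100, m = 5000, seed = 6)   # many markers: K close to I
  set.seed(7)
  y <- rnorm(100)
  fit <- reml_single_trait(y, K)
  expect_true(fit$boundary)
  expect_lt(fit$h2, 0.05)
})

test_that("REML recovers simulated heritability and ignores location shifts", {
  K <- random_grm(300, m = 800, seed = 10)
  est <- vapply(1:8, function(s)
    reml_single_trait(simulate_gblup_trait(K, 0.5, seed = s)$y, K)$h2,
    numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
  sim <- simulate_gblup_trait(K, 0.5, seed = 1)
  f1 <- reml_single_trait(sim$y, K)
  f2 <- reml_single_trait(sim$y + 57, K)
  expect_equal(f1$sigma2_a, f2$sigma2_a, tolerance = 1e-6)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
})

test_that("rrBLUP closed form matches hand arithmetic and infinite shrinkage", {
  ## 2 lines x 1 marker, y = (1,-1), z = (1,-1), lambda = 1:
  ## u = z'(zz' + I)^{-1} y; zz' = [[1,-1],[-1,1]], add I, invert by hand
  ## -> u = 2/3, GEBVs (2/3, -2/3)
  sol <- solve_rrblup(c(1, -1), matrix(c(1, -1), 2, 1), lambda = 1)
  expect_equal(unname(sol$u), 2 / 3, tolerance = 1e-12)
  expect_equal(sol$gebv, c(2 / 3, -2 / 3), tolerance = 1e-12)
  set.seed(5)
  Z <- matrix(rnorm(30 * 20), 30, 20)
  y <- rnorm(30, sd = 2)
  big <- solve_rrblup(y, Z, lambda = 1e12)
  expect_lt(max(abs(big$u)), 1e-6 * sd(y))
  ## marker-side normal-equation oracle: u = (Z'Z + lambda I)^{-1} Z' y_c
  lam <- 3.7
  mine <- solve_rrblup(y, Z, lam)
  yc <- y - mean(y)
  u_or <- solve(crossprod(Z) + lam * diag(20), crossprod(Z, yc))
  expect_equal(mine$u, drop(u_or), tolerance = 1e-8)
})

test_that("rrBLUP and GBLUP give identical predictions (random instances)", {
  for (s in 1:5) {
    set.seed(s)
    n <- 40; p <- 60
    M <- matrix(rbinom(n * p, 2, 0.4), n, p)
    Z <- scale(M, center = TRUE, scale = FALSE)
    y <- rnorm(n)
    lam <- exp(runif(1, -1, 3))
    rr <- solve_rrblup(y, Z, lam)
    cc <- sum(colMeans(M) / 2 * (1 - colMeans(M) / 2)) * 2
    G <- tcrossprod(Z) / cc
    gh <- G %*% solve(G + (lam / cc) * diag(n), y - mean(y))
    expect_equal(rr$gebv, drop(gh), tolerance = 1e-8)
  }
})

test_that("index regression handles exact, degenerate and intercept-only designs", {
  set.seed(9)
  X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("NDVI", "NWI", "PRI")))
  y <- 2 + 3 * X[, 1]                       # exact in one index
  fit <- fit_sri_regression(y, X)
  expect_equal(unname(fit$coefficients), c(2, 3, 0, 0), tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  ## intercept-only: fitted values are the mean
  f0 <- fit_sri_regression(y, X[, 0, drop = FALSE])
  expect_equal(unname(f0$fitted.values), rep(mean(y), 50), tolerance = 1e-12)
  ## duplicated column is a named error
  expect_error(fit_sri_regression(y, cbind(X, NDVI2 = X[, 1])), "NDVI2")
  expect_error(fit_sri_regression(y[1:3], X[1:3, ]), "n >")
})

test_that("covariate GS reduces to plain REML and matches the dense GLS oracle", {
  K <- random_grm(40, seed = 12)
  sim <- simulate_gblup_trait(K, 0.6, seed = 13)
  ## X = intercept only: identical to the univariate path
  f0 <- fit_covariate_gs(sim$y, matrix(nrow = 40, ncol = 0), K)
  u0 <- reml_single_trait(sim$y, K)
  expect_equal(f0$vc$sigma2_a, u0$sigma2_a, tolerance = 1e-10)
  expect_equal(f0$vc$loglik, u0$loglik, tolerance = 1e-10)
  ## dense-inversion oracle at the fitted variance components
  set.seed(14)
  Xs <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("NDVI", "NWI")))
  y <- sim$y + Xs %*% c(0.5, -0.2)
  fit <- fit_covariate_gs(y, Xs, K)
  orc <- dense_gblup_oracle(drop(y), K, cbind(1, Xs),
                            fit$vc$sigma2_a, fit$vc$sigma2_e)
  expect_equal(unname(fit$beta), unname(orc$beta), tolerance = 1e-8)
  expect_equal(unname(fit$gebv), unname(orc$g), tolerance = 1e-8)
  ## noiseless covariate recovery
  yn <- drop(2.0 * Xs[, 1])
  fn <- fit_sri_regression(yn, Xs)
  expect_equal(unname(fn$coefficients["NDVI"]), 2.0, tolerance = 1e-8)
  expect_error(fit_covariate_gs(y, cbind(Xs, NWI2 = Xs[, 2]), K), "NWI2")
})

test_that("univariate GBLUP matches the dense mixed-model oracle", {
  K <- random_grm(45, seed = 20)
  sim <- simulate_gblup_trait(K, 0.4, seed = 21)
  fit <- reml_single_trait(sim$y, K)
  alpha <- phenogs:::gblup_alpha(fit, K, sim$y)
  orc <- dense_gblup_oracle(sim$y, K, matrix(1, 45, 1),
                            fit$sigma2_a, fit$sigma2_e)
  expect_equal(drop(K %*% alpha), orc$g, tolerance = 1e-8)
  expect_equal(unname(fit$beta), unname(orc$beta), tolerance = 1e-8)
})

test_that("EM-REML log-likelihood is monotone and matches a dense evaluation", {
  K <- random_grm(60, seed = 30)
  H <- matrix(c(0.5, 0.3, 0.3, 0.8), 2)
  R <- matrix(c(0.5, 0.1, 0.1, 0.2), 2)
  sim <- simulate_bivariate(K, H, R, seed = 31)
  fit <- suppressWarnings(fit_multitrait_gs(sim$Y, K))
  expect_true(all(diff(fit$loglik_trace) > -1e-7))
  ## canonical-transform likelihood equals the dense projected likelihood
  ll_dense <- dense_mt_loglik(sim$Y, K, fit$H, fit$R)
  expect_equal(fit$loglik, ll_dense, tolerance = 1e-6)
})

test_that("EM-REML converges to a local maximum of the restricted likelihood", {
  ## instance large enough that the optimum is interior, not on the PSD edge
  K <- random_grm(180, m = 500, seed = 33)
  sim <- simulate_bivariate(K, matrix(c(0.5, 0.3, 0.3, 0.8), 2),
                            matrix(c(0.5, 0.1, 0.1, 0.3), 2), seed = 34)
  fit <- fit_multitrait_gs(sim$Y, K, tol = 1e-9, max_iter = 20000)
  expect_true(fit$converged)
  set.seed(35)
  for (i in 1:5) {
    P <- matrix(rnorm(4, 0, 0.03), 2); P <- (P + t(P)) / 2
    expect_gte(fit$loglik + 1e-5, dense_mt_loglik(sim$Y, K, fit$H + P, fit$R))
    expect_gte(fit$loglik + 1e-5, dense_mt_loglik(sim$Y, K, fit$H, fit$R + P))
  }
})

test_that("multi-trait BLUP with partial records matches the dense oracle", {
  K <- random_grm(48, seed = 40)
  sim <- simulate_bivariate(K, matrix(c(0.6, 0.35, 0.35, 0.9), 2),
                            matrix(c(0.4, 0.05, 0.05, 0.2), 2), seed = 41)
  Y <- sim$Y
  Y[41:48, 1] <- NA                       # unphenotyped primary for 8 lines
  fit <- fit_multitrait_gs(Y, K)
  orc <- dense_mt_oracle(Y, K, fit$H, fit$R)
  expect_equal(unname(fit$mu), orc$mu, tolerance = 1e-8)
  expect_equal(unname(fit$gebv), orc$gebv, tolerance = 1e-8)
})

test_that("multi-trait degenerate cases behave as documented", {
  K <- random_grm(50, seed = 50)
  sim <- simulate_bivariate(K, diag(c(0.5, 0.5)), diag(c(0.5, 0.5)), seed = 51)
  ## duplicated trait: genetic correlation pinned at the boundary
  Ydup <- cbind(A = sim$Y[, 1], B = sim$Y[, 1])
  fdup <- suppressWarnings(fit_multitrait_gs(Ydup, K, tol = 1e-10,
                                             max_iter = 10000))
  expect_gt(fdup$rg[1, 2], 0.99)
  expect_true(fdup$rg[1, 2] <= 1)
  expect_true(fdup$rg_boundary[1, 2])
  ## zero-variance trait is an error
  Yz <- cbind(A = sim$Y[, 1], B = rep(1, 50))
  expect_error(fit_multitrait_gs(Yz, K), "zero variance")
  ## iteration cap returns the last iterate with a warning
  expect_warning(fit_multitrait_gs(sim$Y, K, max_iter = 3), "iteration cap")
})

test_that("independent traits make multi-trait GEBVs match univariate GBLUP", {
  K <- random_grm(200, m = 600, seed = 60)
  sim <- simulate_bivariate(K, diag(c(0.5, 0.6)), diag(c(0.5, 0.4)), seed = 61)
  fit2 <- fit_multitrait_gs(sim$Y, K)
  u <- reml_single_trait(sim$Y[, 1], K)
  g_uni <- drop(K %*% phenogs:::gblup_alpha(u, K, sim$Y[, 1]))
  ## correlation distance between the two prediction vectors
  expect_lt(1 - cor(fit2$gebv[, 1], g_uni), 0.02)
})

test_that("a single-trait fit reduces to the univariate REML path", {
  K <- random_grm(150, m = 500, seed = 70)
  sim <- simulate_gblup_trait(K, 0.5, seed = 71)
  mt <- fit_multitrait_gs(matrix(sim$y, dimnames = list(NULL, "y")), K,
                          tol = 1e-10, max_iter = 10000)
  un <- reml_single_trait(sim$y, K)
  expect_equal(drop(mt$H), un$sigma2_a, tolerance = 1e-3)
  expect_equal(drop(mt$R), un$sigma2_e, tolerance = 1e-3)
  expect_equal(mt$loglik, un$loglik, tolerance = 1e-6)
})
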