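test_that("config validation rejects malformed inputs", {
  bad <- matrix(c(1, 0.9, 0.9, 1), 2); bad[1, 2] <- 0.5  # asymmetric
  expect_error(tiny_config(trait_names = c("A", "B"),
                           target_h2 = c(A = .5, B = .5),
                           genetic_corr = bad), "symmetric")
  expect_error(tiny_config(trait_names = c("A", "B"),
                           target_h2 = c(A = .5, B = .5),
                           genetic_corr = matrix(c(1, 2, 2, 1), 2)),
               "\\[-1, 1\\]")
  notpsd <- matrix(c(1, .99, -.99, .99, 1, .99, -.99, .99, 1), 3)
  expect_error(tiny_config(trait_names = c("A", "B", "C"),
                           target_h2 = c(A = .5, B = .5, C = .5),
                           genetic_corr = notpsd), "semi-definite")
  expect_error(tiny_config(target_h2 = c(yield = 1.2, GPC = .5)), "\\[0, 1\\]")
  expect_error(tiny_config(check_fraction = 1.1), "check_fraction")
})

test_that("residual heterozygosity matches the single-locus selfing Markov chain", {
  ## brute-force oracle: states (AA, Aa, aa), selfing transition matrix
  P <- matrix(c(1, 0, 0,
                0.25, 0.5, 0.25,
                0, 0, 1), 3, 3, byrow = TRUE)
  het_after <- function(g) {
    v <- c(0, 1, 0)   # F1 heterozygous
    for (i in seq_len(g)) v <- drop(v %*% P)
    v[2]
  }
  expect_equal(het_after(5), 0.5^5)  # oracle agrees with the closed form
  for (g in c(3L, 5L)) {
    cfg <- sim_config(n_families = 10, lines_per_family = 25, n_markers = 800,
                      n_chromosomes = 8, selfing_generations = g, seed = 101 + g)
    geno <- simulate_nam_genotypes(cfg)
    expect_lt(abs(residual_heterozygosity(geno) - het_after(g)), 0.01)
  }
})

test_that("identical founders give a monomorphic, invariant population", {
  cfg <- tiny_config(founder_freq_range = c(1, 1))
  geno <- simulate_nam_genotypes(cfg)
  expect_true(all(geno == geno[1, 1]))
  f <- colMeans(geno) / 2
  expect_true(all(pmin(f, 1 - f) == 0))
})

test_that("the generator is seed-deterministic with named substreams", {
  cfg <- tiny_config(seed = 99)
  g1 <- simulate_nam_genotypes(cfg)
  g2 <- simulate_nam_genotypes(cfg)
  expect_identical(unclass(g1), unclass(g2))
  t1 <- simulate_traits(g1, cfg)
  t2 <- simulate_traits(g2, cfg)
  expect_identical(t1$values, t2$values)
  expect_false(identical(unclass(g1),
                         unclass(simulate_nam_genotypes(tiny_config(seed = 100)))))
})

test_that("trait simulation honours heritability targets and records exact truth", {
  cfg <- tiny_config(trait_names = c("A", "B"),
                     target_h2 = c(A = 1, B = 0.4), env_mean_sd = 0)
  geno <- simulate_nam_genotypes(cfg)
  st <- simulate_traits(geno, cfg)
  ## h2 = 1: phenotype equals the true breeding value exactly
  v <- st$values[match(rownames(geno), st$values$genotype_id), ]
  expect_equal(v$A, unname(st$truth$true_breeding_values[, "A"]), tolerance = 1e-12)
  ## truth invariant: TBV = centred dosages %*% marker effects
  W <- scale(unclass(geno)[, ], center = TRUE, scale = FALSE)
  expect_equal(st$truth$true_breeding_values,
               W %*% st$truth$true_marker_effects, tolerance = 1e-10)
  expect_error(simulate_traits(structure(NA * unclass(geno)[, ]), cfg), "missing")
})

test_that("realised genetic correlation of breeding values matches its target", {
  gc <- matrix(c(1, .7, .7, 1), 2)
  cfg <- sim_config(n_families = 50, lines_per_family = 20, n_markers = 600,
                    n_chromosomes = 6, trait_names = c("A", "B"),
                    target_h2 = c(A = .5, B = .5), genetic_corr = gc,
                    n_environments = 1, seed = 21)
  st <- simulate_traits(simulate_nam_genotypes(cfg), cfg)
  expect_lt(abs(st$truth$realized_genetic_corr[1, 2] - 0.7), 0.05)
  cfg0 <- sim_config(n_families = 50, lines_per_family = 20, n_markers = 600,
                     n_chromosomes = 6, trait_names = c("A", "B"),
                     target_h2 = c(A = .5, B = .5), n_environments = 1, seed = 22)
  st0 <- simulate_traits(simulate_nam_genotypes(cfg0), cfg0)
  expect_lt(abs(st0$truth$realized_genetic_corr[1, 2]), 0.07)
})

test_that("field layout replicates checks and keeps entries unique", {
  expect_equal(checks_per_block(0.15, 17), 3)   # 3 checks in 20 plots
  expect_equal(checks_per_block(0.1, 5), 2)     # floor of 2 for replication
  cfg <- tiny_config(block_sd = 0, plot_error_sd = 0)
  geno <- simulate_nam_genotypes(cfg)
  st <- simulate_traits(geno, cfg)
  plots <- simulate_field_layout(st$values, cfg)
  entries <- plots[!plots$is_check, ]
  expect_false(anyDuplicated(entries$genotype_id) > 0)
  expect_setequal(entries$genotype_id,
                  st$values$genotype_id[!st$values$is_check])
  ## every block carries every check
  tab <- table(plots$block, plots$genotype_id)[, unique(plots$genotype_id[plots$is_check])]
  expect_true(all(tab >= 1))
  ## zero block effects + zero plot error: plot value equals genotype value
  m <- merge(entries, st$values, by = "genotype_id")
  expect_equal(m$yield.x, m$yield.y, tolerance = 1e-12)
})

test_that("emitted spectra carry the latent index targets and stay in (0,1)", {
  cfg <- tiny_config(seed = 5)
  n <- 500
  set.seed(2)
  targets <- data.frame(plot_id = sprintf("P%03d", 1:n), stage = "heading",
                        NDVI = rnorm(n), NWI = rnorm(n), PRI = rnorm(n))
  refl <- simulate_reflectance(targets, cfg)
  bands <- as.matrix(refl[grep("^R[0-9]+$", names(refl))])
  expect_true(all(bands > 0 & bands < 1))
  idx <- compute_indices(refl)
  expect_gt(cor(targets$NDVI, idx$NDVI), 0.9)
  expect_gt(cor(targets$NWI, idx$NWI), 0.9)
  expect_gt(cor(targets$PRI, idx$PRI), 0.9)
  ## no latent variation -> identical spectra, zero index variance
  flat <- data.frame(plot_id = sprintf("P%03d", 1:20), stage = "heading",
                     NDVI = rep(0.5, 20), NWI = rep(0.1, 20), PRI = rep(0, 20))
  r0 <- simulate_reflectance(flat, cfg, noise_sd = 0)
  i0 <- compute_indices(r0)
  expect_equal(var(i0$NDVI), 0, tolerance = 1e-20)
  expect_equal(var(i0$GNDVI), 0, tolerance = 1e-20)
})
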