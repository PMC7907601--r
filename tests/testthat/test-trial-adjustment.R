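## hand-built augmented design: `shift` is added to every plot of block B2
make_acbd <- function(shift = 0, entry_values = c(e1 = 1, e2 = 2, e3 = 3, e4 = 4),
                      check_values = c(c1 = 0.5, c2 = 1.5), noise = 0) {
  ents <- names(entry_values)
  plots <- rbind(
    data.frame(environment = "env1", block = "B1",
               genotype_id = c(ents[1:2], names(check_values)),
               is_check = c(FALSE, FALSE, TRUE, TRUE),
               y = c(entry_values[1:2], check_values)),
    data.frame(environment = "env1", block = "B2",
               genotype_id = c(ents[3:4], names(check_values)),
               is_check = c(FALSE, FALSE, TRUE, TRUE),
               y = c(entry_values[3:4], check_values) + shift))
  if (noise > 0) plots$y <- plots$y + rnorm(nrow(plots), 0, noise)
  plots
}

test_that("BLUEs equal raw values when block effects are zero", {
  b <- fit_acbd_blue(make_acbd(shift = 0), "y")
  ent <- b[!b$is_check, ]
  expect_equal(ent$value[match(c("e1", "e2", "e3", "e4"), ent$genotype_id)],
               c(1, 2, 3, 4), tolerance = 1e-12)
})

test_that("a block shift is removed exactly (two-block hand oracle)", {
  ## oracle by hand: with checks repeated identically in both blocks, the
  ## least-squares block contrast equals the shift b, so entries in block 2
  ## come out b lower than their raw values relative to block-1 entries
  shift <- 0.8
  b <- fit_acbd_blue(make_acbd(shift = shift), "y")
  ent <- b[!b$is_check, ]
  v <- ent$value[match(c("e1", "e2", "e3", "e4"), ent$genotype_id)]
  ## e3 raw = 3 + shift; after adjustment the spacing e1..e4 is restored
  expect_equal(diff(v), c(1, 1, 1), tolerance = 1e-10)
  ## check BLUEs are block-free means
  chk <- b[b$is_check, ]
  expect_equal(diff(sort(chk$value)), 1, tolerance = 1e-10)
})

test_that("single-block designs return observations unchanged in rank", {
  plots <- data.frame(environment = "env1", block = "B1",
                      genotype_id = c("e1", "e2", "c1", "c1x"),
                      is_check = c(FALSE, FALSE, TRUE, TRUE),
                      y = c(3, 1, 2, 2.5))
  b <- fit_acbd_blue(plots, "y")
  ent <- b[!b$is_check, ]
  expect_equal(ent$value[match(c("e1", "e2"), ent$genotype_id)], c(3, 1))
})

test_that("degenerate designs are rejected with informative errors", {
  p <- make_acbd()
  p2 <- p[!(p$is_check & p$block == "B2"), ]     # block without any check
  expect_error(fit_acbd_blue(p2, "y"), "without checks")
  p3 <- rbind(p, p[p$genotype_id == "e1", ])     # duplicated entry
  expect_error(fit_acbd_blue(p3, "y"), "duplicated")
})

test_that("adjustment preserves within-block ranking of entries", {
  set.seed(31)
  cfg <- tiny_config(block_sd = 1, plot_error_sd = 0.3)
  st <- simulate_traits(simulate_nam_genotypes(cfg), cfg)
  plots <- simulate_field_layout(st$values, cfg)
  b <- fit_acbd_blue(plots, "yield")
  m <- merge(plots[!plots$is_check, ], b[!b$is_check, ],
             by = c("environment", "genotype_id"))
  for (bl in unique(m$block)) {
    sub <- m[m$block == bl, ]
    expect_equal(order(sub$yield), order(sub$value))
  }
})

test_that("broad-sense heritability hits its boundaries and recovers truth", {
  set.seed(7)
  ng <- 60
  gv <- rnorm(ng)
  plots <- data.frame(environment = "env1",
                      block = rep(c("B1", "B2"), each = ng),
                      genotype_id = rep(sprintf("g%02d", 1:ng), 2),
                      is_check = TRUE, y = rep(gv, 2))
  ## zero residual variance
  expect_gt(broad_sense_h2(plots, "y")$H2, 0.999)
  ## zero genotype variance: replicates share nothing beyond noise
  plots$y <- rnorm(nrow(plots))
  expect_lt(broad_sense_h2(plots, "y")$H2, 0.1)
  ## no replication at all
  p1 <- data.frame(environment = "env1", block = "B1",
                   genotype_id = sprintf("g%02d", 1:20), is_check = FALSE,
                   y = rnorm(20))
  expect_error(broad_sense_h2(p1, "y"), "replicat")
})

test_that("H2 = 0.5 is recovered from balanced replicated trials", {
  ## sigma2_g = sigma2_e = 1, 150 genotypes x 2 reps, mean over seeds
  est <- vapply(1:8, function(s) {
    set.seed(s)
    ng <- 150
    gv <- rnorm(ng)
    plots <- data.frame(environment = "env1",
                        block = rep(c("B1", "B2"), each = ng),
                        genotype_id = rep(sprintf("g%03d", 1:ng), 2),
                        is_check = TRUE,
                        y = rep(gv, 2) + rnorm(2 * ng) +
                          rep(c(0, 0.5), each = ng))
    broad_sense_h2(plots, "y")$H2
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("REML matches lme4 on a replicated trial and ignores constants", {
  set.seed(12)
  ng <- 80
  gv <- rnorm(ng, sd = sqrt(2))
  plots <- data.frame(environment = "env1",
                      block = rep(c("B1", "B2", "B3"), each = ng),
                      genotype_id = rep(sprintf("g%03d", 1:ng), 3),
                      is_check = TRUE,
                      y = rep(gv, 3) + rnorm(3 * ng) +
                        rep(c(0, 1, -0.5), each = ng))
  ours <- broad_sense_h2(plots, "y")
  lm4 <- lme4::lmer(y ~ block + (1 | genotype_id), data = plots, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(ours$sigma2_g, vc$vcov[vc$grp == "genotype_id"], tolerance = 1e-4)
  expect_equal(ours$sigma2_e, vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
  shifted <- plots; shifted$y <- shifted$y + 100
  expect_equal(broad_sense_h2(shifted, "y")$H2, ours$H2, tolerance = 1e-6)
})
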