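test_that("null studies are seeded, sorted, and match the configured spectrum", {
  cfg <- null_sim_config(100, 50, chrom_lengths = c(50L, 50L), maf_max = 0.05)
  s1 <- simulate_null_study(cfg, seed = 5)
  s2 <- simulate_null_study(cfg, seed = 5)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$mafs, s2$mafs)
  expect_equal(dim(s1$genotypes$dosage), c(100L, 100L))
  expect_equal(s1$phenotype$n_case, 50L)
  # positions strictly increasing within each chromosome
  for (ch in c("1", "2")) {
    pos <- s1$genotypes$sites$pos[s1$genotypes$sites$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
  expect_true(all(s1$mafs >= cfg$maf_min & s1$mafs <= cfg$maf_max))
  # uniform spectrum: sample mean MAF ~ midpoint
  cfgu <- null_sim_config(100, 50, chrom_lengths = 10000L, maf_max = 0.05,
                          maf_min = 0.01, maf_spectrum = "uniform")
  su <- simulate_null_study(cfgu, seed = 6)
  expect_equal(mean(su$mafs), 0.03, tolerance = 0.02)
})

test_that("null genotypes are Hardy-Weinberg binomial draws", {
  cfg <- null_sim_config(2000, 1000, chrom_lengths = 50L, maf_max = 0.4,
                         maf_min = 0.1)
  s <- simulate_null_study(cfg, seed = 21)
  # chi-square goodness of fit of dosage counts against Binomial(2, maf)
  pvals <- vapply(seq_len(50), function(v) {
    obs <- tabulate(s$genotypes$dosage[v, ] + 1L, 3L)
    expe <- 2000 * dbinom(0:2, 2, s$mafs[v])
    suppressWarnings(chisq.test(obs, p = expe / sum(expe))$p.value)
  }, numeric(1))
  expect_gt(mean(pvals > 0.01), 0.9)
})

test_that("logistic intercept recovers the closed form with no causal effects", {
  base <- null_sim_config(200, 100, chrom_lengths = 50L, maf_max = 0.05)
  cfg <- disease_sim_config(base, prevalence = 0.01, window_size = 10,
                            pdv = 0, pnv = 1, or_interval = c(1, 1))
  s <- simulate_disease_study(cfg, seed = 3)
  # all ORs are 1: beta0 = logit(K) = ln(1/99)
  expect_equal(s$truth$beta0, log(1 / 99), tolerance = 1e-6)
  expect_true(all(s$truth$log_or == 0))
  expect_equal(s$phenotype$n_case, 100L)
})

test_that("population incidence matches the prevalence before sampling", {
  base <- null_sim_config(100, 50, chrom_lengths = 30L, maf_max = 0.05)
  cfg <- disease_sim_config(base, prevalence = 0.1, window_size = 15,
                            pdv = 0.5, pnv = 0.2, or_interval = c(2, 4))
  s <- simulate_disease_study(cfg, seed = 9)
  # re-simulate the population disease probability at the fitted intercept
  set.seed(99)
  maf <- s$truth$mafs[s$truth$site_index]
  g <- matrix(rbinom(200000 * 15, 2, rep(maf, each = 200000)), 200000, 15)
  inc <- mean(plogis(s$truth$beta0 + as.vector(g %*% s$truth$log_or)))
  expect_equal(inc, 0.1, tolerance = 0.01)
})

test_that("a single causal variant reproduces its odds ratio in the sample", {
  # K = 0.5, OR fixed at 3: the case/control allelic odds ratio is
  # approximately 3 in a large sample
  base <- null_sim_config(6000, 3000, chrom_lengths = 1L, maf_max = 0.05,
                          maf_min = 0.04)
  cfg <- disease_sim_config(base, prevalence = 0.5, window_size = 1,
                            pdv = 1, pnv = 0, or_interval = c(3, 3))
  s <- simulate_disease_study(cfg, seed = 17)
  r <- sma_test(s$genotypes$dosage[1, ], s$phenotype)
  expect_equal(unname(r$or), 3, tolerance = 0.25)
})

test_that("protective variants get reciprocal odds ratios", {
  base <- null_sim_config(100, 50, chrom_lengths = 20L, maf_max = 0.05)
  cfg <- disease_sim_config(base, prevalence = 0.1, window_size = 20,
                            pdv = 0, pnv = 0, or_interval = c(2, 5))
  s <- simulate_disease_study(cfg, seed = 23)
  expect_true(all(s$truth$role == "protective"))
  expect_true(all(s$truth$log_or <= log(1 / 2) + 1e-12 &
                  s$truth$log_or >= log(1 / 5) - 1e-12))
})

test_that("with no effects, case and control genotypes are exchangeable", {
  base <- null_sim_config(400, 200, chrom_lengths = 40L, maf_max = 0.2,
                          maf_min = 0.05)
  cfg <- disease_sim_config(base, prevalence = 0.05, window_size = 20,
                            pdv = 0, pnv = 1, or_interval = c(1, 1))
  s <- simulate_disease_study(cfg, seed = 31)
  p <- sma_scan(s$genotypes, s$phenotype)$sites$p
  # association p values behave like a null sample
  expect_gt(min(p), 1e-4 / length(p))
  expect_lt(mean(p < 0.1), 0.25)
})

test_that("power estimation handles degenerate thresholds and trends", {
  base <- null_sim_config(60, 30, chrom_lengths = 30L, maf_max = 0.1)
  cfg <- disease_sim_config(base, prevalence = 0.1, window_size = 10,
                            pdv = 0.7, pnv = 0.3, or_interval = c(2, 2))
  pw1 <- estimate_power(cfg, alpha_gecs = 1, alpha_sma = 1, n_reps = 3,
                        maf_t = 0.1, seed = 2)
  expect_equal(pw1$power_gecs, 1)
  expect_equal(pw1$power_sma, 1)
  pw0 <- estimate_power(cfg, alpha_gecs = 0, alpha_sma = 0, n_reps = 3,
                        maf_t = 0.1, seed = 2)
  expect_equal(pw0$power_gecs, 0)
  expect_equal(pw0$power_sma, 0)
  expect_error(estimate_power(cfg, 1, 1, n_reps = 0), "n_reps")
})
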