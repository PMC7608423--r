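test_that("label permutation preserves counts, is seeded, and is uniform", {
  ph <- phenotype(c(1, 1, 0, 0))
  set.seed(1)
  p1 <- permuted_phenotype(ph)
  expect_equal(p1$n_case, 2L)
  expect_equal(p1$n_control, 2L)
  set.seed(1)
  expect_identical(permuted_phenotype(ph)$labels, p1$labels)
  # all 6 distinct arrangements of 2 cases among 4 appear ~ uniformly
  set.seed(42)
  draws <- replicate(6000, paste(permuted_phenotype(ph)$labels, collapse = ""))
  freq <- table(draws)
  expect_length(freq, 6L)
  expect_true(all(abs(freq / 6000 - 1 / 6) < 0.02))
})

test_that("min-p distribution is reproducible and respects its invariants", {
  cfg <- null_sim_config(60, 30, chrom_lengths = c(50L, 50L), maf_max = 0.2)
  study <- simulate_null_study(cfg, seed = 19)
  panels <- build_panels(study$genotypes, maf_t = c(0.05, 0.2))
  sc <- scan_study(panels, study$phenotype, keep_carriers = TRUE)
  d1 <- minp_distribution(sc, study$phenotype, r = 25,
                          genotypes = study$genotypes, include_sma = TRUE,
                          seed = 4)
  d2 <- minp_distribution(sc, study$phenotype, r = 25,
                          genotypes = study$genotypes, include_sma = TRUE,
                          seed = 4)
  expect_identical(d1$minp_combined, d2$minp_combined)
  expect_identical(d1$minp_sma, d2$minp_sma)
  expect_length(d1$minp_combined, 25L)
  expect_true(all(d1$minp_combined > 0 & d1$minp_combined <= 1))
  # combined minimum is the minimum over per-threshold minima, replicate-wise
  expect_equal(d1$minp_combined,
               apply(d1$minp_by_threshold, 1L, min))
  expect_error(minp_distribution(sc, study$phenotype, r = 0), "r must be")
})

test_that("fast permutation path is bit-identical to re-running the scan", {
  set.seed(77)
  for (rep in 1:10) {
    N <- 24
    carr1 <- random_carriers(N, sample(8:20, 1), runif(1, 0.1, 0.4))
    carr2 <- random_carriers(N, sample(8:20, 1), runif(1, 0.1, 0.4))
    panels <- list(mk_panel(carr1, maf_t = 0.1, chrom = "1"),
                   mk_panel(carr2, maf_t = 0.1, chrom = "2"))
    ph <- phenotype(rep(c(1, 0), each = 12))
    sc <- scan_study(panels, ph, keep_carriers = TRUE)
    fast <- minp_distribution(sc, ph, r = 15, seed = rep)
    set.seed(rep)
    naive <- vapply(1:15, function(k) {
      scan_study(panels, permuted_phenotype(ph))$min_p_combined
    }, numeric(1))
    expect_identical(unname(fast$minp_combined), naive)
  }
})

test_that("single-marker min-p fast path matches per-variant retesting", {
  cfg <- null_sim_config(40, 20, chrom_lengths = 30L, maf_max = 0.3)
  study <- simulate_null_study(cfg, seed = 8)
  panels <- build_panels(study$genotypes, maf_t = 0.3)
  sc <- scan_study(panels, study$phenotype, keep_carriers = TRUE)
  fast <- minp_distribution(sc, study$phenotype, r = 10,
                            genotypes = study$genotypes, include_sma = TRUE,
                            seed = 3)
  set.seed(3)
  naive <- vapply(1:10, function(k) {
    php <- permuted_phenotype(study$phenotype)
    sma_scan(study$genotypes, php)$min_p
  }, numeric(1))
  expect_equal(unname(fast$minp_sma), naive, tolerance = 1e-12)
})

test_that("empirical thresholds use the floor(fwer*(r+1)) order statistic", {
  mk_dist <- function(minp) {
    structure(list(r = length(minp), minp_combined = minp,
                   minp_by_threshold = matrix(minp, ncol = 1,
                                              dimnames = list(NULL, "0.05")),
                   minp_sma = NULL, n_case = 10, n_individuals = 20,
                   seed = NULL),
              class = "gecs_minp")
  }
  # r = 19, fwer = 0.05 -> k = 1: alpha is the smallest min-p
  d19 <- mk_dist(seq(0.05, 0.95, length.out = 19))
  th <- suppressWarnings(empirical_threshold(d19, 0.05))
  expect_equal(th$k, 1)
  expect_equal(th$alpha_combined, 0.05)
  # r = 999 -> k = 50
  set.seed(10)
  d999 <- mk_dist(runif(999))
  th999 <- empirical_threshold(d999, 0.05)
  expect_equal(th999$k, 50)
  expect_equal(th999$alpha_combined, sort(d999$minp_combined)[50])
  # r too small for the requested level
  expect_error(empirical_threshold(mk_dist(runif(10)), 0.05), "increase r")
  # degenerate: all min-p equal 1
  expect_warning(thd <- empirical_threshold(mk_dist(rep(1, 99)), 0.5),
                 "degenerate")
  expect_equal(thd$alpha_combined, 1)
})

test_that("adjusted p values count replicates and stay consistent with alpha", {
  set.seed(12)
  minp <- runif(999)
  d <- structure(list(r = 999, minp_combined = minp,
                      minp_by_threshold = matrix(minp, ncol = 1,
                                                 dimnames = list(NULL, "0.05")),
                      minp_sma = runif(999), n_case = 10, n_individuals = 20,
                      seed = NULL),
                 class = "gecs_minp")
  expect_equal(adjusted_p(min(minp) / 2, d), 1 / 1000)
  expect_equal(adjusted_p(1, d), 1)
  # direct count at an interior point
  p0 <- sort(minp)[500]
  expect_equal(adjusted_p(p0, d), (1 + 500) / 1000)
  # monotone in p
  ps <- sort(runif(20))
  expect_true(all(diff(adjusted_p(ps, d)) >= 0))
  # consistency: adjusting alpha recovers ~ fwer
  th <- empirical_threshold(d, 0.05)
  expect_equal(adjusted_p(th$alpha_combined, d), (1 + 50) / 1000)
})
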