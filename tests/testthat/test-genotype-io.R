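test_that("VCF genotypes decode to ALT dosages with missing passthrough", {
  f <- tempfile(fileext = ".vcf")
  gt <- rbind(c("0/0", "0/1", "1/1"),
              c("./.", "0/1", "0|0"))
  write_vcf_fixture(f, chrom = c("1", "1"), pos = c(100, 200),
                    ref = c("A", "G"), alt = c("T", "C"), gt = gt,
                    samples = c("s1", "s2", "s3"))
  g <- read_vcf(f)
  expect_equal(g$dosage[1, ], c(0L, 1L, 2L))
  expect_true(is.na(g$dosage[2, 1]))
  expect_equal(g$dosage[2, 2:3], c(1L, 0L))
  expect_equal(g$samples, c("s1", "s2", "s3"))
  expect_equal(g$sites$pos, c(100L, 200L))
})

test_that("multiallelic records are skipped with a warning", {
  f <- tempfile(fileext = ".vcf")
  gt <- rbind(c("0/1", "0/0"), c("0/1", "1/1"), c("0/0", "0/1"),
              c("1/1", "0/0"), c("0/0", "0/0"))
  write_vcf_fixture(f, chrom = rep("1", 5), pos = (1:5) * 100,
                    ref = rep("A", 5),
                    alt = c("T", "T,C", "G", "T,G", "C"), gt = gt,
                    samples = c("s1", "s2"))
  expect_warning(g <- read_vcf(f), "multiallelic")
  expect_equal(nrow(g$dosage), 3L)   # 3 biallelic of 5 records
  expect_equal(g$sites$pos, c(100L, 300L, 500L))
})

test_that("sample subsetting honors order and flags unknown samples", {
  f <- tempfile(fileext = ".vcf")
  gt <- rbind(c("0/0", "0/1", "1/1"))
  write_vcf_fixture(f, "1", 100, "A", "T", gt, c("s1", "s2", "s3"))
  g <- read_vcf(f, samples = c("s3", "s1"))
  expect_equal(g$dosage[1, ], c(2L, 0L))
  expect_error(read_vcf(f, samples = c("s1", "sX")), "sX")
})

test_that("phenotype files align to genotype sample order and validate", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("s3\t0", "s1\t1", "s2\t1", "s4\t0"), f)
  ph <- read_phenotype(f, c("s1", "s2", "s3", "s4"))
  expect_equal(ph$labels, c(1L, 1L, 0L, 0L))
  expect_equal(ph$n_case, 2L)
  writeLines(c("s1\t1", "s1\t0", "s2\t0"), f)
  expect_error(read_phenotype(f, c("s1", "s2")), "duplicated.*s1")
  writeLines(c("s1\t1", "s2\t2"), f)
  expect_error(read_phenotype(f, c("s1", "s2")), "status.*s2")
  writeLines(c("s1\t1"), f)
  expect_error(read_phenotype(f, c("s1", "s2")), "s2")
})

test_that("minor-allele orientation and inclusive MAF filtering", {
  # 4 individuals; rows: ALT freq 3/8 (dropped at 0.05), singleton het,
  # REF-minor site with dosages 2,2,2,1
  dos <- rbind(c(0L, 1L, 2L, 0L),
               c(0L, 0L, 0L, 1L),
               c(2L, 2L, 2L, 1L))
  sites <- data.frame(chrom = "1", pos = c(10L, 20L, 30L), id = ".",
                      ref = "A", alt = "C", stringsAsFactors = FALSE)
  g <- structure(list(dosage = dos, sites = sites,
                      samples = paste0("s", 1:4)),
                 class = "gecs_genotypes")
  p05 <- build_panels(g, maf_t = 0.05)
  expect_length(p05, 0L)  # 0.375 > 0.05; 0.125 > 0.05 for both rare sites
  p5 <- build_panels(g, maf_t = 0.5)
  expect_length(p5, 1L)
  expect_equal(nrow(p5[[1]]$sites), 3L)
  # singleton het: carrier set 0001
  expect_equal(p5[[1]]$carriers[, 2], c(FALSE, FALSE, FALSE, TRUE))
  # REF-minor site: carrier of >= 1 REF allele is the dosage-1 individual
  expect_equal(p5[[1]]$carriers[, 3], c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(p5[[1]]$sites$maf[3], 0.125)
})

test_that("monomorphic sites are dropped and missing counts as non-carrier", {
  dos <- rbind(c(0L, 0L, 0L, 0L),
               c(2L, 2L, 2L, 2L),
               c(NA, 1L, 0L, 0L))
  sites <- data.frame(chrom = "1", pos = c(1L, 2L, 3L), id = ".",
                      ref = "A", alt = "C", stringsAsFactors = FALSE)
  g <- structure(list(dosage = dos, sites = sites,
                      samples = paste0("s", 1:4)),
                 class = "gecs_genotypes")
  p <- build_panels(g, maf_t = 0.5)
  expect_equal(nrow(p[[1]]$sites), 1L)
  # MAF over non-missing alleles: 1 / 6
  expect_equal(p[[1]]$sites$maf, 1 / 6)
  expect_equal(p[[1]]$carriers[, 1], c(FALSE, TRUE, FALSE, FALSE))
})

test_that("panels at nested thresholds are nested", {
  cfg <- null_sim_config(50, 25, chrom_lengths = 200L, maf_max = 0.4)
  study <- simulate_null_study(cfg, seed = 31)
  key <- function(p) paste(p$sites$chrom, p$sites$pos)
  panels <- build_panels(study$genotypes, maf_t = c(0.01, 0.03, 0.05))
  by_t <- split(panels, vapply(panels, `[[`, numeric(1), "maf_t"))
  keys <- lapply(by_t, function(ps) unlist(lapply(ps, key)))
  if (length(keys) == 3L) {
    expect_true(all(keys[["0.01"]] %in% keys[["0.03"]]))
    expect_true(all(keys[["0.03"]] %in% keys[["0.05"]]))
  }
  # every retained site satisfies the panel invariants
  for (p in panels) {
    expect_true(all(p$sites$maf > 0 & p$sites$maf <= p$maf_t))
    expect_true(all(colSums(p$carriers) >= 1))
    expect_true(all(diff(p$sites$pos) > 0))
  }
})

test_that("simulated studies round-trip through VCF + phenotype files", {
  cfg <- null_sim_config(30, 15, chrom_lengths = c(40L, 40L), maf_max = 0.3)
  study <- simulate_null_study(cfg, seed = 77)
  fv <- tempfile(fileext = ".vcf")
  fp <- tempfile(fileext = ".tsv")
  write_vcf(study$genotypes, fv)
  write_phenotype(study$phenotype, study$genotypes$samples, fp)
  g2 <- read_vcf(fv)
  ph2 <- read_phenotype(fp, g2$samples)
  expect_equal(g2$dosage, study$genotypes$dosage, ignore_attr = TRUE)
  expect_equal(ph2$labels, study$phenotype$labels)
  p1 <- build_panels(study$genotypes, maf_t = 0.3)
  p2 <- build_panels(g2, maf_t = 0.3)
  expect_equal(length(p1), length(p2))
  for (k in seq_along(p1))
    expect_equal(unname(p1[[k]]$carriers), unname(p2[[k]]$carriers))
})
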