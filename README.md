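# gecs — Genomic Exhaustive Collapsing Scan

Region-based rare-variant association scans usually test a priori fixed
bins (genes, sliding windows). When the truly associated region only partly
overlaps a chosen bin, the signal is diluted or split, inflating the type II
error. `gecs` implements the exhaustive alternative for case–control
studies: it considers **every** contiguous bin of rare variants on a
chromosome, and makes this feasible by testing only the *locally distinct*
bins — bins whose carrier set changes both when the leftmost variant is
removed and when the rightmost variant is extended. All other bins share a
carrier set, and therefore a test result, with an emitted bin.

The package is aimed at statistical geneticists analysing case–control
sequence or imputed genotype data, and at methodologists studying
significance thresholds and power for region-agnostic rare-variant testing.

## Method

For variants `i..j` on a chromosome, let `B_ij` be the set of individuals
carrying at least one minor allele at any of those variants (a bit-vector
over the `N` samples). The collapsing test (COLL) compares carriers and
non-carriers between cases and controls with the 1-df Pearson χ² on the
2×2 table; for a bin with `m` carriers of whom `a` are cases,

    χ² = N (ad − bc)² / ((a+b)(c+d)(a+c)(b+d)),

with `b = m − a`, `c = n_case − a`, `d = n_control − b`. A chromosome with
`n` variants has `n(n+1)/2` contiguous bins, but the scan maintains running
unions per start index and skips any bin whose carrier set equals that of a
neighbouring bin, typically reducing the number of evaluated tests by
orders of magnitude. Minor-allele frequency thresholds (default 0.01, 0.03,
0.05) define "rare"; the scan runs once per threshold and the results are
combined.

Family-wise error is controlled empirically: case–control labels are
permuted `R` times, the genome-wide minimum p is recorded per replicate,
and the significance threshold is the `floor(fwer·(R+1))`-th smallest
minimum p. Because bin enumeration does not depend on the phenotype, only
case-carrier counts are recomputed per replicate — results are identical to
re-running the whole scan on every permuted dataset. Overlapping
significant bins are merged into blocks, each reported through its most
significant member. A single-marker analysis (SMA, allelic χ²) comparator
and a synthetic-study simulator (neutral 1/x frequency spectrum,
Hardy–Weinberg genotypes, logistic disease model) for threshold and power
experiments are included.

## Worked example

Simulate a null study (200 individuals, half cases, two chromosomes of 500
rare variants) and run the full pipeline:

```r
library(gecs)
cfg   <- null_sim_config(200, 100, chrom_lengths = c(500, 500), maf_max = 0.05)
study <- simulate_null_study(cfg, seed = 42)
fit   <- gecs(study$genotypes, study$phenotype, permutations = 999, seed = 42)
print(fit)
```

```
Genomic exhaustive collapsing scan (GECS)

Genomic exhaustive collapsing scan
  100 cases / 100 controls; MAF thresholds: 0.01, 0.03, 0.05
  locally distinct bins tested: 97252 (naive contiguous bins: 390461)
  smallest bin p value (all thresholds combined): 0.000499

Empirical significance thresholds (FWER 0.05, r = 999):
  combined: 7.324e-06
  MAF_T = 0.01: 4.523e-05
  MAF_T = 0.03: 1.824e-05
  MAF_T = 0.05: 1.39e-05
  SMA: 0.0006231

Significant bins: 0, merged into 0 block(s)
SMA: smallest single-marker p = 0.00338 (threshold 0.0006231)
```

Reading the output: of the 390,461 contiguous bins implied by 1,000
variants at three thresholds, only 97,252 are locally distinct and were
tested. The permutation-calibrated genome-wide threshold for the combined
scan (7.3 × 10⁻⁶) is stricter than any per-threshold value, which is in
turn stricter than the single-marker threshold — the multiple-testing cost
of scanning all bins. On this null dataset the smallest observed bin p
(5 × 10⁻⁴) is far above the threshold, so nothing is declared significant,
as it should be.

Real data enter through standard formats:

```r
geno <- read_vcf("study.vcf")
ph   <- read_phenotype("study.pheno.tsv", geno$samples)
fit  <- gecs(geno, ph, permutations = 999, seed = 1)
write_results(fit$scan, fit$thresholds, fit$blocks, "out/run1", dist = fit$dist)
```

or through the command-line wrapper:

```sh
exec/gecs scan --vcf study.vcf --pheno study.pheno.tsv \
    --maf 0.01,0.03,0.05 --permutations 999 --fwer 0.05 --seed 1 \
    --out out/run1 --sma
```

which writes a bin TSV, a block TSV, a BED file of significant blocks, and
a JSON run manifest.

## Package tour

| Function | Purpose |
| --- | --- |
| `read_vcf()`, `read_phenotype()` | genotype/phenotype input |
| `build_panels()` | minor-allele orientation, MAF filtering, carrier sets |
| `scan_chromosome()`, `scan_study()` | locally distinct bin enumeration + COLL tests |
| `brute_force_scan()` | explicit n(n+1)/2 enumeration (oracle for small panels) |
| `minp_distribution()`, `empirical_threshold()`, `adjusted_p()` | permutation FWER control |
| `merge_significant_blocks()`, `write_results()` | block merging and output |
| `simulate_null_study()`, `simulate_disease_study()`, `estimate_power()` | simulator |
| `gecs()` | the full pipeline, returning a classed result with `print`/`summary`/`plot` |

See `vignettes/gecs-methods.Rmd` for the modelling assumptions, parameter
choices and limitations.
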