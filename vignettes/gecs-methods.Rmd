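---
title: "Methods and design of the genomic exhaustive collapsing scan"
author: "gecs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the genomic exhaustive collapsing scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Region-based rare-variant association tests aggregate variants in physical
proximity under the assumption that nearby rare alleles have similar
phenotypic effects. The collapsing test (COLL) is the simplest such
aggregation: an individual is a *carrier* of a region if they carry at
least one minor allele at any variant in it, and association is assessed by
the 1-df Pearson chi-square on the 2×2 carrier-status × case-status table.
For a region with carrier set of size $m$, of whom $a$ are cases,

$$\chi^2 \;=\; \frac{N\,(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)},
\qquad b = m-a,\; c = n_\mathrm{case}-a,\; d = n_\mathrm{control}-b .$$

No continuity correction is applied; the permutation calibration described
below absorbs finite-sample miscalibration of the raw statistic.

Instead of fixing analysis regions in advance, the scan considers **all**
contiguous bins $i..j$ of the $n$ rare variants on a chromosome — there are
$n(n+1)/2$ of them — but evaluates the statistic only on the *locally
distinct* bins: bins whose carrier set $B_{ij}$ differs both from
$B_{(i+1)j}$ (dropping the leftmost variant) and from $B_{i(j+1)}$
(extending to the right). Any other bin shares its carrier set, hence its
test result, with a bin that is emitted. The enumeration keeps, for each
start $i$, the running union $U = B_{ij}$ and the trailing union
$V = B_{(i+1)j}$ (defined as empty while $j = i$):

* if $U = V$ or $U$ covers all $N$ individuals, the inner loop **breaks**
  (every continuation of this start is covered by the next start, or is
  degenerate);
* else if the next variant's carriers are already contained in $U$, the bin
  is **skipped** (it reappears, unchanged, at larger $j$);
* otherwise the bin is **emitted** and tested.

The check order matters when both conditions hold at once: the break test
runs first. At the last variant of a chromosome the skip test is vacuous,
so a bin that survived the break test is emitted — otherwise the rightmost
maximal bins would be lost. Because $V \subseteq U \subseteq U \cup
B_{j+1}$, all set comparisons reduce to popcount comparisons; carrier sets
are bit-vectors packed into 32-bit words, and this inner loop (plus the
permutation counting kernel) is the only compiled code in the package. Unions
are monotone in $j$, so a single left-to-right pass per start suffices.
The full-carrier bin is never tested (its table is degenerate and its p
value would be 1). A bin appearing under two MAF thresholds counts as two
tests, mirroring how per-threshold and combined results are reported.
Identical carrier sets emitted at different loci are deliberately *not*
deduplicated: each emission is its own test (they share a p value).

## Carrier-set panels

Minor alleles are oriented per site on cases and controls combined: the
minor allele is the one with sample frequency ≤ 0.5 (a tie at exactly 0.5
keeps ALT as minor). Monomorphic sites and sites with MAF above the
threshold are dropped; retention is inclusive (MAF ≤ threshold). Missing
genotypes count as non-carriers and are excluded from the allele-frequency
denominator — conservative for a carrier-based test, and it keeps carrier
sets well defined. Computing MAF on the combined sample (rather than
controls only) makes the panels invariant under phenotype permutation,
which is what allows the permutation engine to reuse the bin enumeration;
computing MAF on controls only would invalidate that reuse. Multiallelic
VCF records are skipped with a warning rather than decomposed, since
decomposition changes carrier semantics. Position ties are kept in input
order; the scan operates on variant indices, not base-pair positions.

## Permutation calibration

Case–control labels are permuted (sampling without replacement, preserving
$n_\mathrm{case}$), and the genome-wide minimum p over all bins (per
threshold, combined, and optionally over single markers) is recorded per
replicate. The empirical threshold at family-wise error rate $\alpha_F$ is
the $k$-th smallest of the $R$ minima with $k = \lfloor \alpha_F (R+1)
\rfloor$, and significance is declared for observed $p <$ threshold
(strict) — the standard ordering that guarantees FWER ≤ nominal.
Permutation-adjusted p values use the companion estimator
$p_\mathrm{adj} = (1 + \#\{\text{min-p} \le p\})/(R+1)$, so adjusting the
threshold itself recovers ≈ $\alpha_F$.

Since bin enumeration is phenotype-free, the fast path enumerates bins once
and recomputes only the case-carrier counts (a masked popcount) per
replicate, taking the per-replicate maximum chi-square in compiled code.
The compiled chi-square mirrors the R expression's floating-point operation
order, and all intermediate products are exactly representable integers at
the sample sizes involved, so the fast path is bit-identical to naively
re-running the scan per replicate — a contract the test suite checks
directly. A threshold whose panel contains no variants contributes a
minimum p of 1 (no test performed) rather than an error.

## The simulator

The generator defines the package's study conditions.

* **Null model.** Per-variant MAFs are drawn from a density $\propto 1/x$
  truncated to $[1/(2N), 0.05]$ by default — the $1/x$ shape is the
  classical neutral frequency spectrum, and the lower bound is the
  frequency of a singleton allele; a uniform spectrum is available for
  sensitivity checks. Genotypes are independent Hardy–Weinberg draws,
  dosage ~ Binomial(2, MAF); positions are strictly increasing with ~100 bp
  mean spacing. Under the null the labels carry no information, so the
  first $n_\mathrm{case}$ individuals are cases.
* **Disease model.** A window of $w$ consecutive variants on one chromosome
  is causal. Each causal variant is independently detrimental (probability
  PDV, per-allele OR uniform on the configured interval), neutral
  (probability PNV, OR = 1), or protective (remainder, OR = reciprocal of a
  draw from the interval). Disease probability is logistic in the summed
  dosage-weighted log-ORs; the intercept is solved numerically (Monte-Carlo
  expectation of 50,000 population burden scores + root finding) so the
  population prevalence equals $K$. Individuals are rejection-sampled until
  the case and control quotas are met. Only the causal window affects
  disease risk, so the sampler draws causal-window genotypes during
  rejection and fills in the remaining (independent) variants afterwards —
  distributionally identical to rejecting fully simulated genomes, and an
  order of magnitude cheaper at low prevalence.

What the simulator does **not** emulate: linkage disequilibrium between
sites, realistic demography or selection, genotyping error, covariate
structure, or quantitative phenotypes. Passing tests therefore demonstrate
algorithmic correctness and calibration under idealised independent-variant
data, not performance on real cohorts, where LD will correlate
neighbouring bins and population structure can inflate the raw statistic.

## Study designs used by the packaged experiments

Problem sizes were chosen as desk-scale stand-ins for genome-wide studies.

* **FWER calibration** (`fwer_calibration_experiment()`): N = 200 with 100
  cases, 2 chromosomes × 500 variants, 1/x spectrum capped at 0.05, three
  MAF thresholds (0.01/0.03/0.05), R = 999 permutations, and 400
  independent null studies to measure the realised family-wise error.
  At 400 studies the binomial 95% band around a true 5% rate reaches ≈
  7.7%.
* **Power comparison**: prevalence K = 0.01, N = 2000 with 1000 cases, one
  chromosome of 200 variants, causal window w = 20, PDV = 0.7, PNV = 0.3,
  OR fixed at 1.5, 200 replicates; thresholds calibrated on a matching null
  study with R = 199 permutations ($k = \lfloor 0.05 \cdot 200 \rfloor =
  10$). The chromosome length and the balanced case fraction are the
  package's own desk-scale choices; the remaining parameters follow the
  power-study grid the method is normally evaluated on. The comparison
  asserts the qualitative claim — the exhaustive scan is at least as
  powerful as single-marker analysis for small effect sizes — not absolute
  power values, which depend on the generative details.

## Numerical and design choices

* **Chi-square degeneracies.** Any zero row/column margin yields statistic
  0, p = 1. The statistic is computed in double precision from integer
  counts; at N ≤ 2000 every intermediate product is below $2^{53}$, so the
  computation is exact up to the final division.
* **Calibration of the raw test.** Under the permutation
  (hypergeometric) null the uncorrected chi-square p value is *not*
  uniformly super-uniform: with few carriers the discrete test is
  conservative (ECDF(0.05) ≈ 0.03 at N = 200, m = 12), while at
  intermediate carrier counts it can exceed nominal (≈ 0.073 at m = 30).
  This is classical Pearson-vs-exact behaviour, and it is exactly why
  genome-wide thresholds are taken from the permutation distribution rather
  than from the chi-square tail. Under the unconditional null (carrier
  status independent of phenotype, margins free) the rejection rate is
  within Monte-Carlo noise of nominal across realistic carrier
  probabilities.
* **Odds ratios.** Woolf (log-OR normal) 95% intervals; any zero cell makes
  OR and CI undefined (reported as `.` in output files) rather than
  Haldane-corrected — the package does not invent estimates.
* **Single-marker comparator.** The allelic 2×2 chi-square on minor-allele
  counts over *all* polymorphic variants (no MAF filter), matching how a
  single genome-wide single-marker threshold is reported alongside
  per-threshold scan results. Genotypic or carrier-based variants of the
  single-marker test would change only this comparator, not the scan.
* **Indexing.** Variant and individual indices are 1-based throughout, as
  idiomatic in R; bin coordinates in output files are 1-based inclusive
  base-pair positions of the first and last variant, and BED output
  converts to 0-based half-open.
* **Block merging.** Significant bins are grouped per chromosome by
  transitive interval overlap (touching endpoints merge), across MAF
  thresholds; each block reports its smallest-p bin, ties broken by smaller
  span then leftmost start.
* **Reproducibility.** All randomness flows through R's session RNG from a
  single user-visible seed; two runs with the same seed and inputs produce
  byte-identical output files. The manifest records parameters, not
  timestamps, to keep outputs deterministic.

## Known limitations

* COLL dichotomizes by carrier status and cannot distinguish carriers of
  one versus several minor alleles, loses power when effect directions are
  mixed within a bin, and takes no covariates; the scan's pruning argument
  is specific to carrier-set unions and does not transfer directly to
  regression-type or variance-component tests.
* Permutation calibration assumes exchangeability of labels — population
  structure or covariate-driven confounding violates it.
* The quadratic-time brute-force oracle is intended for small panels only
  (it exists to verify the scan, not to analyse data).
* Memory for the permutation fast path grows with the number of distinct
  bins (one packed bit-vector per bin); at the packaged study designs this
  is tens of megabytes, but genome-scale data may require scanning
  chromosomes in batches.
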