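# Collapsing (COLL) and single-marker association statistics.

#' Case-control phenotype
#'
#' Construct a binary phenotype aligned to the genotype sample order.
#'
#' @param labels integer/numeric vector of 0 (control) / 1 (case), one entry
#'   per genotyped individual, in genotype sample order.
#' @return An object of class `gecs_phenotype`: list with `labels`
#'   (integer vector), `n_case`, `n_control`.
#' @examples
#' ph <- phenotype(c(1, 1, 0, 0))
#' ph$n_case
#' @export
phenotype <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) < 2L || anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("phenotype labels must be 0/1 with no missing values")
  n_case <- sum(labels == 1L)
  n_control <- sum(labels == 0L)
  if (n_case < 1L || n_control < 1L)
    stop("need at least one case and one control")
  structure(list(labels = labels, n_case = n_case, n_control = n_control),
            class = "gecs_phenotype")
}

#' @export
print.gecs_phenotype <- function(x, ...) {
  cat(sprintf("Case-control phenotype: %d cases, %d controls (N = %d)\n",
              x$n_case, x$n_control, length(x$labels)))
  invisible(x)
}

# Vectorized 1-df Pearson chi-square statistic on 2x2 cell counts.
# Degenerate margins give statistic 0. The evaluation order of the
# floating-point expression is mirrored bit-for-bit in the C++ permutation
# kernel; do not "simplify" it.
chi2_stat <- function(a, b, c, d) {
  # promote to double (dims preserved) so large-N products cannot overflow
  a <- a + 0.0; b <- b + 0.0; c <- c + 0.0; d <- d + 0.0
  N <- a + b + c + d
  t <- a * d - b * c
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  ifelse(den > 0, N * (t * t) / den, 0)
}

#' Pearson 1-df chi-square test on a 2x2 contingency table
#'
#' The collapsing test statistic: no continuity correction, upper-tail p from
#' the chi-square distribution with 1 degree of freedom. A table with a zero
#' row or column margin yields statistic 0 and p = 1.
#'
#' @param a,b,c,d non-negative cell counts: case carriers, control carriers,
#'   case non-carriers, control non-carriers (vectorized).
#' @return list with `statistic` and `p`.
#' @examples
#' pearson_chi2_1df(25, 10, 75, 90)  # statistic ~ 7.79, p ~ 0.0052
#' @export
pearson_chi2_1df <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  stat <- chi2_stat(a, b, c, d)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Woolf odds ratio and 95 percent confidence interval for a 2x2 table
#'
#' OR = ad / (bc); the confidence interval is the log-OR normal (Woolf)
#' interval exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)). Any zero cell
#' makes the estimate undefined (`NA`); no continuity correction is applied.
#'
#' @inheritParams pearson_chi2_1df
#' @return list with `or` and `ci` (length-2 lower/upper); vectorized inputs
#'   give vector `or`, `ci_low`, `ci_high`.
#' @examples
#' odds_ratio_woolf(25, 10, 75, 90)  # OR 3.0, CI ~ [1.355, 6.642]
#' @export
odds_ratio_woolf <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  or <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  z <- qnorm(0.975)
  lo <- exp(log(or) - z * se)
  hi <- exp(log(or) + z * se)
  if (length(or) == 1L)
    list(or = or, ci = c(lo, hi))
  else
    list(or = or, ci_low = lo, ci_high = hi)
}

#' Collapsing (COLL) test of a carrier set against a phenotype
#'
#' Dichotomizes individuals by carrier status (at least one minor allele in
#' the region) and applies the 1-df Pearson chi-square to the resulting 2x2
#' carrier-by-status table. Counting case carriers is the only
#' phenotype-dependent step; the result depends on the carrier set only
#' through its size and its overlap with the cases.
#'
#' @param carriers logical vector over individuals (TRUE = carrier), aligned
#'   to `phenotype`.
#' @param phenotype a [phenotype()] object.
#' @return list with `statistic`, `p`, `or`, `ci`, and the table cells
#'   `a`, `b`, `c`, `d`.
#' @export
coll_test <- function(carriers, phenotype) {
  stopifnot(inherits(phenotype, "gecs_phenotype"))
  carriers <- as.logical(carriers)
  if (length(carriers) != length(phenotype$labels))
    stop("carrier set length does not match phenotype length")
  if (anyNA(carriers)) stop("carrier set must not contain NA")
  a <- sum(carriers & phenotype$labels == 1L)
  m <- sum(carriers)
  b <- m - a
  c <- phenotype$n_case - a
  d <- phenotype$n_control - b
  ct <- pearson_chi2_1df(a, b, c, d)
  orw <- odds_ratio_woolf(a, b, c, d)
  list(statistic = ct$statistic, p = ct$p, or = orw$or, ci = orw$ci,
       a = a, b = b, c = c, d = d)
}

#' Single-marker allelic association test
#'
#' The single-marker-analysis (SMA) comparator: a 1-df Pearson chi-square on
#' the 2x2 allelic table of minor vs. major allele counts in cases and
#' controls. Missing genotypes are excluded from both numerator and
#' denominator. If every genotype is missing the test is degenerate
#' (statistic 0, p = 1).
#'
#' @param dosages per-individual minor-allele dosage (0/1/2, `NA` = missing),
#'   aligned to `phenotype`.
#' @inheritParams coll_test
#' @return list with `statistic`, `p`, `or` (allelic odds ratio), `ci`.
#' @export
sma_test <- function(dosages, phenotype) {
  stopifnot(inherits(phenotype, "gecs_phenotype"))
  if (length(dosages) != length(phenotype$labels))
    stop("dosage length does not match phenotype length")
  case <- phenotype$labels == 1L
  obs <- !is.na(dosages)
  a <- sum(dosages[case & obs])            # minor alleles in cases
  b <- sum(dosages[!case & obs])           # minor alleles in controls
  c <- 2 * sum(case & obs) - a             # major alleles in cases
  d <- 2 * sum(!case & obs) - b
  ct <- pearson_chi2_1df(a, b, c, d)
  orw <- odds_ratio_woolf(a, b, c, d)
  list(statistic = ct$statistic, p = ct$p, or = orw$or, ci = orw$ci,
       a = a, b = b, c = c, d = d)
}

#' Genome-wide single-marker scan
#'
#' Runs the allelic single-marker test on every polymorphic variant of the
#' genotype table (dosages oriented to the minor allele first).
#'
#' @param genotypes a `gecs_genotypes` object.
#' @param phenotype a [phenotype()] object.
#' @return list with `sites` (data.frame chrom/pos/id/maf/chi2/p) and
#'   `min_p` (1 when no polymorphic variants exist).
#' @export
sma_scan <- function(genotypes, phenotype) {
  stopifnot(inherits(genotypes, "gecs_genotypes"),
            inherits(phenotype, "gecs_phenotype"))
  o <- site_maf(genotypes$dosage)
  poly <- which(!is.na(o$maf) & o$maf > 0)
  if (!length(poly)) {
    return(list(sites = data.frame(), min_p = 1))
  }
  dos <- genotypes$dosage[poly, , drop = FALSE]
  flip <- which(!o$minor_is_alt[poly])
  dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
  case <- phenotype$labels == 1L
  d0 <- dos
  miss <- is.na(d0)
  d0[miss] <- 0L
  a <- as.vector(d0 %*% case)
  n_obs_case <- as.vector((!miss) %*% case)
  b <- rowSums(d0) - a
  cc <- 2 * n_obs_case - a
  d <- 2 * (rowSums(!miss) - n_obs_case) - b
  stat <- chi2_stat(a, b, cc, d)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  list(sites = data.frame(chrom = genotypes$sites$chrom[poly],
                          pos = genotypes$sites$pos[poly],
                          id = genotypes$sites$id[poly],
                          maf = o$maf[poly], chi2 = stat, p = p,
                          stringsAsFactors = FALSE),
       min_p = min(p))
}
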