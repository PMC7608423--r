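# Permutation-based family-wise error rate control: min-p distributions,
# empirical thresholds, and adjusted p values.

#' Permute case-control labels
#'
#' Uniform random permutation of the phenotype labels; case and control
#' counts are preserved. Uses the session RNG (set a seed with [set.seed()]
#' for reproducibility).
#'
#' @param phenotype a [phenotype()] object.
#' @return a new [phenotype()] object with permuted labels.
#' @export
permuted_phenotype <- function(phenotype) {
  stopifnot(inherits(phenotype, "gecs_phenotype"))
  phenotype(phenotype$labels[sample.int(length(phenotype$labels))])
}

# Per-variant SMA chi-square statistics for a set of case masks.
# dosage: variants x individuals; masks: individuals x r logical.
# Returns an r-vector of max chi2 over variants (0 if no variants).
sma_perm_max_chi2 <- function(dosage, masks) {
  if (nrow(dosage) == 0L) return(rep(0, ncol(masks)))
  d0 <- dosage
  miss <- is.na(d0)
  d0[miss] <- 0L
  storage.mode(d0) <- "double"
  obs <- matrix(as.double(!miss), nrow(dosage), ncol(dosage))
  m <- matrix(as.double(masks), ncol = ncol(masks))
  a <- d0 %*% m                         # minor alleles in cases
  n_obs_case <- obs %*% m               # non-missing case genotypes
  tot_minor <- rowSums(d0)
  tot_obs <- rowSums(obs)
  b <- tot_minor - a
  cc <- 2 * n_obs_case - a
  d <- 2 * (tot_obs - n_obs_case) - b
  stat <- chi2_stat(a, b, cc, d)
  apply(stat, 2L, max)
}

#' Permutation distribution of genome-wide minimum p values
#'
#' For each of `r` replicates, permutes the case-control labels and records
#' the smallest COLL p value over all locally distinct bins, per MAF
#' threshold and combined (and, optionally, the smallest single-marker p).
#' Because bin enumeration is phenotype-independent, bins are enumerated once
#' and only the case-carrier counts are recomputed per replicate; results are
#' identical to re-running the full scan on each permuted phenotype.
#'
#' @param scan a `gecs_scan` from [scan_study()] run with
#'   `keep_carriers = TRUE` (or a list of panels, which will be scanned).
#' @param phenotype a [phenotype()] object.
#' @param r number of permutation replicates (>= 1).
#' @param genotypes optional `gecs_genotypes`; required when
#'   `include_sma = TRUE` (SMA runs on all polymorphic variants).
#' @param include_sma also record per-replicate minimum single-marker p.
#' @param seed optional integer seed (applied with [set.seed()]).
#' @return object of class `gecs_minp`: list with `r`, `minp_combined`,
#'   `minp_by_threshold` (matrix, one column per threshold), `minp_sma`
#'   (or `NULL`), `n_case`, `n_individuals`, `seed`.
#' @export
minp_distribution <- function(scan, phenotype, r, genotypes = NULL,
                              include_sma = FALSE, seed = NULL) {
  if (r < 1L) stop("r must be >= 1")
  stopifnot(inherits(phenotype, "gecs_phenotype"))
  if (!inherits(scan, "gecs_scan"))
    scan <- scan_study(scan, phenotype, keep_carriers = TRUE)
  if (is.null(scan$bin_index))
    stop("scan must be produced with keep_carriers = TRUE")
  if (include_sma && is.null(genotypes))
    stop("include_sma = TRUE needs the genotype table")
  if (!is.null(seed)) set.seed(seed)
  N <- scan$n_individuals
  n_case <- phenotype$n_case
  # draw all permutations up front (column = replicate)
  perm_case <- matrix(FALSE, N, r)
  for (k in seq_len(r))
    perm_case[, k] <- permuted_phenotype(phenotype)$labels == 1L
  masks <- pack_bits_cpp(perm_case)
  thresholds <- scan$maf_t
  max_chi2 <- matrix(0, r, length(thresholds),
                     dimnames = list(NULL, as.character(thresholds)))
  for (bi in scan$bin_index) {
    if (length(bi$popcount) == 0L) next
    col <- as.character(bi$maf_t)
    mc <- perm_max_chi2_cpp(bi$words, bi$popcount, masks, n_case, N)
    max_chi2[, col] <- pmax(max_chi2[, col], mc)
  }
  minp_by_threshold <- pchisq(max_chi2, df = 1, lower.tail = FALSE)
  minp_combined <- apply(minp_by_threshold, 1L, min)
  minp_sma <- NULL
  if (include_sma) {
    o <- site_maf(genotypes$dosage)
    poly <- !is.na(o$maf) & o$maf > 0
    dos <- genotypes$dosage[poly, , drop = FALSE]
    # orient to minor allele so dosages count minor alleles
    flip <- which(!o$minor_is_alt[poly])
    dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
    mx <- sma_perm_max_chi2(dos, perm_case)
    minp_sma <- pchisq(mx, df = 1, lower.tail = FALSE)
  }
  structure(list(r = r, minp_combined = minp_combined,
                 minp_by_threshold = minp_by_threshold, minp_sma = minp_sma,
                 n_case = n_case, n_individuals = N, seed = seed),
            class = "gecs_minp")
}

#' @export
print.gecs_minp <- function(x, ...) {
  cat(sprintf("Permutation min-p distribution: r = %d replicates\n", x$r))
  cat(sprintf("  combined min-p range: [%.3g, %.3g]\n",
              min(x$minp_combined), max(x$minp_combined)))
  if (!is.null(x$minp_sma))
    cat(sprintf("  SMA min-p range: [%.3g, %.3g]\n",
                min(x$minp_sma), max(x$minp_sma)))
  invisible(x)
}

#' Empirical significance thresholds at a nominal FWER
#'
#' The threshold alpha is the k-th smallest permutation min-p with
#' k = floor(fwer * (r + 1)); an observed p is declared significant when
#' p < alpha (strict). Computed per MAF threshold, combined, and for SMA when
#' available.
#'
#' @param dist a `gecs_minp` from [minp_distribution()].
#' @param fwer nominal family-wise error rate in (0, 1), default 0.05.
#' @return object of class `gecs_thresholds`: list with `fwer`,
#'   `alpha_combined`, `alpha_by_threshold` (named numeric), `alpha_sma`
#'   (`NA` if SMA was not recorded), `r`, `k`.
#' @export
empirical_threshold <- function(dist, fwer = 0.05) {
  stopifnot(inherits(dist, "gecs_minp"))
  if (fwer <= 0 || fwer >= 1) stop("fwer must be in (0, 1)")
  k <- floor(fwer * (dist$r + 1))
  if (k < 1)
    stop("too few permutation replicates for fwer = ", fwer,
         "; increase r to at least ", ceiling(1 / fwer))
  if (dist$r < 1 / fwer)
    warning("r < 1/fwer; empirical threshold will be coarse")
  kth <- function(x) sort(x, partial = k)[k]
  alpha_combined <- kth(dist$minp_combined)
  alpha_by_threshold <- apply(dist$minp_by_threshold, 2L, kth)
  alpha_sma <- if (is.null(dist$minp_sma)) NA_real_ else kth(dist$minp_sma)
  if (alpha_combined >= 1)
    warning("all permutation min-p values are 1; panels may be degenerate")
  structure(list(fwer = fwer, alpha_combined = alpha_combined,
                 alpha_by_threshold = alpha_by_threshold,
                 alpha_sma = alpha_sma, r = dist$r, k = k),
            class = "gecs_thresholds")
}

#' @export
print.gecs_thresholds <- function(x, ...) {
  cat(sprintf("Empirical significance thresholds (FWER %.3g, r = %d):\n",
              x$fwer, x$r))
  cat(sprintf("  combined: %.4g\n", x$alpha_combined))
  for (nm in names(x$alpha_by_threshold))
    cat(sprintf("  MAF_T = %s: %.4g\n", nm, x$alpha_by_threshold[[nm]]))
  if (!is.na(x$alpha_sma)) cat(sprintf("  SMA: %.4g\n", x$alpha_sma))
  invisible(x)
}

#' Permutation-adjusted p value
#'
#' Standard min-p adjustment: p_adj = (1 + number of replicates with
#' min-p <= p) / (r + 1). Monotone non-decreasing in p.
#'
#' @param p observed p value(s) in (0, 1].
#' @param dist a `gecs_minp` from [minp_distribution()].
#' @param scope which min-p distribution to adjust against: `"combined"`
#'   (default), `"threshold"` (requires `maf_t`), or `"sma"`.
#' @param maf_t MAF threshold selecting the column for `scope = "threshold"`.
#' @return adjusted p value(s).
#' @export
adjusted_p <- function(p, dist, scope = c("combined", "threshold", "sma"),
                       maf_t = NULL) {
  stopifnot(inherits(dist, "gecs_minp"))
  scope <- match.arg(scope)
  ref <- switch(scope,
    combined = dist$minp_combined,
    threshold = {
      if (is.null(maf_t)) stop("scope = 'threshold' needs maf_t")
      dist$minp_by_threshold[, as.character(maf_t)]
    },
    sma = {
      if (is.null(dist$minp_sma)) stop("distribution has no SMA min-p values")
      dist$minp_sma
    })
  vapply(p, function(pp) (1 + sum(ref <= pp)) / (dist$r + 1), numeric(1L))
}
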