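# Top-level pipeline: scan + permutation calibration + block merging.

#' Run the full genomic exhaustive collapsing scan pipeline
#'
#' Builds rare-variant panels at the given MAF thresholds, enumerates and
#' tests all locally distinct bins, calibrates empirical genome-wide
#' significance thresholds from the permutation distribution of minimum
#' p values, and merges overlapping significant bins into blocks.
#'
#' @param genotypes a `gecs_genotypes` object ([read_vcf()] or the
#'   simulator).
#' @param phenotype a [phenotype()] object aligned to the genotype samples.
#' @param maf_t MAF thresholds (default `c(0.01, 0.03, 0.05)`).
#' @param permutations number of label permutations for FWER calibration.
#' @param fwer nominal family-wise error rate (default 0.05).
#' @param sma also run the single-marker comparator and calibrate its
#'   threshold.
#' @param seed optional integer seed governing the permutations.
#' @return object of class `gecs`: list with `scan` (`gecs_scan`), `dist`
#'   (`gecs_minp`), `thresholds` (`gecs_thresholds`), `blocks`
#'   (data.frame), `sma` (single-marker results or `NULL`), and `call`.
#' @examples
#' cfg <- null_sim_config(60, 30, chrom_lengths = c(40, 40), maf_max = 0.2)
#' study <- simulate_null_study(cfg, seed = 1)
#' fit <- gecs(study$genotypes, study$phenotype, maf_t = c(0.05, 0.2),
#'             permutations = 99, seed = 1)
#' print(fit)
#' @export
gecs <- function(genotypes, phenotype, maf_t = c(0.01, 0.03, 0.05),
                 permutations = 999L, fwer = 0.05, sma = TRUE, seed = NULL) {
  stopifnot(inherits(genotypes, "gecs_genotypes"),
            inherits(phenotype, "gecs_phenotype"))
  panels <- build_panels(genotypes, maf_t)
  scan <- scan_study(panels, phenotype, keep_carriers = TRUE)
  dist <- minp_distribution(scan, phenotype, r = permutations,
                            genotypes = genotypes, include_sma = sma,
                            seed = seed)
  thresholds <- empirical_threshold(dist, fwer)
  blocks <- merge_significant_blocks(scan$bins, thresholds$alpha_combined)
  sma_res <- if (sma) sma_scan(genotypes, phenotype) else NULL
  structure(list(scan = scan, dist = dist, thresholds = thresholds,
                 blocks = blocks, sma = sma_res, maf_t = maf_t,
                 call = match.call()),
            class = "gecs")
}

#' @export
print.gecs <- function(x, ...) {
  cat("Genomic exhaustive collapsing scan (GECS)\n\n")
  print(x$scan)
  cat("\n")
  print(x$thresholds)
  n_sig <- sum(x$scan$bins$p < x$thresholds$alpha_combined)
  cat(sprintf("\nSignificant bins: %d, merged into %d block(s)\n",
              n_sig, nrow(x$blocks)))
  if (!is.null(x$sma) && nrow(x$sma$sites))
    cat(sprintf("SMA: smallest single-marker p = %.3g (threshold %.4g)\n",
                x$sma$min_p, x$thresholds$alpha_sma))
  invisible(x)
}

#' @export
summary.gecs <- function(object, ...) {
  print(object)
  if (nrow(object$blocks)) {
    cat("\nBlocks (top bin per block):\n")
    print(object$blocks, row.names = FALSE)
  }
  invisible(object)
}

#' Plot the scan: bin significance along the genome
#'
#' Plots -log10(p) of every locally distinct bin at its midpoint position,
#' one panel color per chromosome, with the combined empirical significance
#' threshold as a horizontal line.
#'
#' @param x a `gecs` object.
#' @param ... passed to [plot()].
#' @export
plot.gecs <- function(x, ...) {
  b <- x$scan$bins
  chroms <- unique(b$chrom)
  col <- (match(b$chrom, chroms) - 1L) %% 2L + 1L
  mid <- (b$pos_start + b$pos_end) / 2
  # lay chromosomes end to end
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(b$pos_end[b$chrom == ch]) * 1.05, numeric(1L))))
  xpos <- mid + offs[match(b$chrom, chroms)]
  graphics::plot(xpos, -log10(b$p), col = c("grey30", "steelblue")[col],
                 pch = 16, cex = 0.5, xlab = "genomic position (bp, concatenated)",
                 ylab = expression(-log[10](italic(p))), ...)
  graphics::abline(h = -log10(x$thresholds$alpha_combined), col = "red",
                   lty = 2)
  invisible(x)
}
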