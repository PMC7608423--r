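# The exhaustive collapsing scan: locally distinct bin enumeration and the
# brute-force oracle.

# Pack a logical case/carrier vector into the 32-bit word layout used by the
# C++ kernels.
pack_mask <- function(x) pack_bits_cpp(matrix(as.logical(x), ncol = 1L))[, 1L]

# Evaluate COLL statistics for bins given case-carrier counts `a` and bin
# carrier sizes `m` (vectorized).
bin_stats <- function(a, m, n_case, n_control) {
  b <- m - a
  c <- n_case - a
  d <- n_control - b
  stat <- chi2_stat(a, b, c, d)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  orw <- odds_ratio_woolf(a, b, c, d)
  data.frame(case_carriers = a, control_carriers = b, chi2 = stat, p = p,
             or = orw$or,
             ci_low = if (length(a) == 1L) orw$ci[1L] else orw$ci_low,
             ci_high = if (length(a) == 1L) orw$ci[2L] else orw$ci_high)
}

#' Scan one chromosome panel for locally distinct bins
#'
#' Enumerates every locally distinct contiguous bin of the panel and tests
#' each with the collapsing chi-square test. For each start index i a running
#' carrier union U over variants i..j and a trailing union V over i+1..j are
#' maintained; the inner loop breaks when U equals V (removing the leftmost
#' variant changes nothing — every continuation is covered by the next start)
#' or when U covers all individuals, skips emission when the next variant's
#' carriers are already contained in U (the bin reappears at larger j), and
#' otherwise emits bin (i, j, U). Since V is a subset of U and U a subset of
#' the extension, equality checks reduce to popcount comparisons.
#'
#' @param panel a `variant_panel` from [build_panels()].
#' @param phenotype a [phenotype()] object aligned to the panel's individuals.
#' @param keep_carriers if `TRUE` attach the packed carrier bitsets of the
#'   emitted bins (needed by the permutation engine) as attribute `bin_index`.
#' @return data.frame with one row per locally distinct bin: `maf_t`, `chrom`,
#'   `i`, `j` (1-based inclusive variant indices), `pos_start`, `pos_end`,
#'   `n_variants`, `n_carriers`, `case_carriers`, `control_carriers`, `chi2`,
#'   `p`, `or`, `ci_low`, `ci_high`.
#' @export
scan_chromosome <- function(panel, phenotype, keep_carriers = FALSE) {
  stopifnot(inherits(panel, "variant_panel"),
            inherits(phenotype, "gecs_phenotype"))
  N <- nrow(panel$carriers)
  if (N != length(phenotype$labels))
    stop("panel and phenotype disagree on the number of individuals")
  if (any(colSums(panel$carriers) == 0L))
    stop("panel contains a variant with an empty carrier set")
  sc <- scan_bins_cpp(panel$carriers)
  nb <- length(sc$i)
  if (nb == 0L) {
    out <- data.frame(maf_t = numeric(), chrom = character(), i = integer(),
                      j = integer(), pos_start = integer(), pos_end = integer(),
                      n_variants = integer(), n_carriers = integer(),
                      case_carriers = integer(), control_carriers = integer(),
                      chi2 = numeric(), p = numeric(), or = numeric(),
                      ci_low = numeric(), ci_high = numeric())
  } else {
    case_mask <- pack_mask(phenotype$labels == 1L)
    a <- count_in_mask_cpp(sc$words, case_mask)
    st <- bin_stats(a, sc$popcount, phenotype$n_case, phenotype$n_control)
    out <- cbind(data.frame(maf_t = panel$maf_t, chrom = panel$chrom,
                            i = sc$i, j = sc$j,
                            pos_start = panel$sites$pos[sc$i],
                            pos_end = panel$sites$pos[sc$j],
                            n_variants = sc$j - sc$i + 1L,
                            n_carriers = sc$popcount,
                            stringsAsFactors = FALSE),
                 st)
  }
  if (keep_carriers)
    attr(out, "bin_index") <- list(words = sc$words, popcount = sc$popcount,
                                   n_individuals = N)
  out
}

#' Brute-force enumeration of all contiguous bins (test oracle)
#'
#' Explicitly enumerates every contiguous bin i..j of the panel — all
#' n(n+1)/2 of them — with its carrier union and COLL test. Quadratic in the
#' number of variants; intended as an independent oracle for small panels.
#'
#' @inheritParams scan_chromosome
#' @return data.frame with one row per bin (`i`, `j`, `n_carriers`,
#'   `carrier_key` — a canonical string key of the carrier set — `chi2`, `p`).
#' @export
brute_force_scan <- function(panel, phenotype) {
  stopifnot(inherits(panel, "variant_panel"),
            inherits(phenotype, "gecs_phenotype"))
  n <- ncol(panel$carriers)
  case <- phenotype$labels == 1L
  rows <- vector("list", n * (n + 1L) / 2L)
  k <- 0L
  for (i in seq_len(n)) {
    U <- rep(FALSE, nrow(panel$carriers))
    for (j in i:n) {
      U <- U | panel$carriers[, j]
      k <- k + 1L
      a <- sum(U & case)
      m <- sum(U)
      st <- pearson_chi2_1df(a, m - a, phenotype$n_case - a,
                             phenotype$n_control - (m - a))
      rows[[k]] <- data.frame(i = i, j = j, n_carriers = m,
                              carrier_key = paste(which(U), collapse = ","),
                              chi2 = st$statistic, p = st$p,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the exhaustive scan over all panels of a study
#'
#' Scans every (chromosome, MAF threshold) panel independently and aggregates
#' the locally distinct bins. A physical bin that appears under two thresholds
#' counts as two tests. Bins never span chromosomes.
#'
#' @param panels list of `variant_panel` objects from [build_panels()].
#' @inheritParams scan_chromosome
#' @return object of class `gecs_scan`: list with `bins` (data.frame over all
#'   panels), `min_p_combined`, `min_p_by_threshold` (named numeric),
#'   `n_bins_total`, `n_bins_naive`, `n_case`, `n_control`,
#'   `n_individuals`, `maf_t`, and (when `keep_carriers`) `bin_index`,
#'   a per-panel list used by [minp_distribution()].
#' @export
scan_study <- function(panels, phenotype, keep_carriers = FALSE) {
  panels <- panels[vapply(panels, function(p) nrow(p$sites) > 0L, logical(1L))]
  if (!length(panels)) stop("no variants pass thresholds")
  per <- lapply(panels, scan_chromosome, phenotype = phenotype,
                keep_carriers = keep_carriers)
  bins <- do.call(rbind, per)
  thresholds <- sort(unique(vapply(panels, `[[`, numeric(1L), "maf_t")))
  min_p_by_threshold <- vapply(thresholds, function(tt) {
    p <- bins$p[bins$maf_t == tt]
    if (length(p)) min(p) else 1
  }, numeric(1L))
  names(min_p_by_threshold) <- as.character(thresholds)
  n_naive <- sum(vapply(panels, function(p) {
    n <- nrow(p$sites); n * (n + 1) / 2
  }, numeric(1L)))
  out <- list(bins = bins,
              min_p_combined = min(min_p_by_threshold),
              min_p_by_threshold = min_p_by_threshold,
              n_bins_total = nrow(bins),
              n_bins_naive = n_naive,
              n_case = phenotype$n_case, n_control = phenotype$n_control,
              n_individuals = length(phenotype$labels),
              maf_t = thresholds)
  if (keep_carriers)
    out$bin_index <- lapply(seq_along(panels), function(k) {
      bi <- attr(per[[k]], "bin_index")
      bi$maf_t <- panels[[k]]$maf_t
      bi$chrom <- panels[[k]]$chrom
      bi
    })
  class(out) <- "gecs_scan"
  out
}

#' @export
print.gecs_scan <- function(x, ...) {
  cat("Genomic exhaustive collapsing scan\n")
  cat(sprintf("  %d cases / %d controls; MAF thresholds: %s\n",
              x$n_case, x$n_control, paste(x$maf_t, collapse = ", ")))
  cat(sprintf("  locally distinct bins tested: %d (naive contiguous bins: %.0f)\n",
              x$n_bins_total, x$n_bins_naive))
  cat(sprintf("  smallest bin p value (all thresholds combined): %.3g\n",
              x$min_p_combined))
  invisible(x)
}

#' @export
summary.gecs_scan <- function(object, n_top = 5L, ...) {
  print(object)
  top <- object$bins[order(object$bins$p), , drop = FALSE]
  top <- utils::head(top, n_top)
  cat(sprintf("\nTop %d bins:\n", nrow(top)))
  print(top[, c("chrom", "pos_start", "pos_end", "maf_t", "n_variants",
                "chi2", "p", "or")], row.names = FALSE)
  invisible(object)
}

# Carrier set (logical vector) of the k-th bin of a scan_chromosome result
# produced with keep_carriers = TRUE. Exposed for tests and inspection.
#' Extract the carrier set of a scanned bin
#'
#' @param bins result of [scan_chromosome()] with `keep_carriers = TRUE`.
#' @param k bin row number.
#' @return logical vector over individuals.
#' @export
bin_carriers <- function(bins, k) {
  bi <- attr(bins, "bin_index")
  if (is.null(bi)) stop("bins were scanned without keep_carriers = TRUE")
  unpack_bits_cpp(bi$words[, k], bi$n_individuals)
}
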