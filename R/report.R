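# Aggregation of significant bins into blocks and standard-format output.

#' Merge overlapping significant bins into blocks
#'
#' Filters bins with p strictly below `alpha`, then groups them per
#' chromosome by transitive base-pair interval overlap (intervals are
#' 1-based inclusive `[pos_start, pos_end]`; touching endpoints count as
#' overlapping). Bins from different MAF thresholds merge together. Each
#' block is reported through its most significant member bin (ties broken by
#' smaller span, then leftmost start).
#'
#' @param bins data.frame of bins as produced by [scan_study()] (needs
#'   columns `chrom`, `pos_start`, `pos_end`, `p`; the top-bin columns are
#'   carried through).
#' @param alpha significance threshold in (0, 1]; strict comparison p < alpha.
#' @return data.frame with one row per block: `chrom`, `span_start`,
#'   `span_end`, `n_bins`, and `top_*` columns describing the top bin.
#'   Zero rows when nothing is significant.
#' @export
merge_significant_blocks <- function(bins, alpha) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  sig <- bins[bins$p < alpha, , drop = FALSE]
  empty <- data.frame(chrom = character(), span_start = integer(),
                      span_end = integer(), n_bins = integer(),
                      top_pos_start = integer(), top_pos_end = integer(),
                      top_maf_t = numeric(), top_n_variants = integer(),
                      top_p = numeric(), top_or = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos_start, s$pos_end), , drop = FALSE]
    # sweep: transitive overlap closure of sorted intervals
    grp <- integer(nrow(s))
    g <- 1L
    cur_end <- s$pos_end[1L]
    grp[1L] <- g
    for (k in seq_len(nrow(s))[-1L]) {
      if (s$pos_start[k] <= cur_end) {
        grp[k] <- g
        cur_end <- max(cur_end, s$pos_end[k])
      } else {
        g <- g + 1L
        grp[k] <- g
        cur_end <- s$pos_end[k]
      }
    }
    for (gg in seq_len(g)) {
      mem <- s[grp == gg, , drop = FALSE]
      top <- mem[order(mem$p, mem$pos_end - mem$pos_start, mem$pos_start), ,
                 drop = FALSE][1L, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, span_start = min(mem$pos_start),
        span_end = max(mem$pos_end), n_bins = nrow(mem),
        top_pos_start = top$pos_start, top_pos_end = top$pos_end,
        top_maf_t = top$maf_t, top_n_variants = top$n_variants,
        top_p = top$p, top_or = top$or, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

fmt_num <- function(x) ifelse(is.na(x), ".", format(x, digits = 8,
                                                    scientific = NA,
                                                    trim = TRUE))

#' Write scan results to disk
#'
#' Writes four files under a common prefix:
#' `<prefix>_bins.tsv` (all significant bins),
#' `<prefix>_blocks.tsv` (one row per merged block),
#' `<prefix>_blocks.bed` (BED3+name; 0-based half-open coordinates), and
#' `<prefix>_manifest.json` (run parameters and thresholds).
#' Undefined odds ratios / confidence bounds are written as `"."`.
#'
#' @param scan a `gecs_scan` from [scan_study()].
#' @param thresholds a `gecs_thresholds` from [empirical_threshold()].
#' @param blocks data.frame from [merge_significant_blocks()].
#' @param out_prefix output path prefix.
#' @param dist optional `gecs_minp` for permutation-adjusted p values.
#' @param manifest named list of extra manifest entries (e.g. seed, r).
#' @return invisibly, the vector of file paths written.
#' @export
write_results <- function(scan, thresholds, blocks, out_prefix, dist = NULL,
                          manifest = list()) {
  stopifnot(inherits(scan, "gecs_scan"), inherits(thresholds, "gecs_thresholds"))
  sig <- scan$bins[scan$bins$p < thresholds$alpha_combined, , drop = FALSE]
  sig <- sig[order(sig$p), , drop = FALSE]
  p_adj <- if (!is.null(dist) && nrow(sig))
    adjusted_p(sig$p, dist, scope = "combined") else rep(NA_real_, nrow(sig))
  bins_tsv <- data.frame(chrom = sig$chrom, pos_start = sig$pos_start,
                         pos_end = sig$pos_end, maf_t = sig$maf_t,
                         n_variants = sig$n_variants,
                         case_carriers = sig$case_carriers,
                         control_carriers = sig$control_carriers,
                         chi2 = fmt_num(sig$chi2), p = fmt_num(sig$p),
                         p_adjusted = fmt_num(p_adj),
                         OR = fmt_num(sig$or), ci_low = fmt_num(sig$ci_low),
                         ci_high = fmt_num(sig$ci_high),
                         stringsAsFactors = FALSE)
  f_bins <- paste0(out_prefix, "_bins.tsv")
  write.table(bins_tsv, f_bins, sep = "\t", quote = FALSE, row.names = FALSE)

  f_blocks <- paste0(out_prefix, "_blocks.tsv")
  blocks_tsv <- blocks
  for (col in c("top_p", "top_or")) blocks_tsv[[col]] <- fmt_num(blocks[[col]])
  write.table(blocks_tsv, f_blocks, sep = "\t", quote = FALSE,
              row.names = FALSE)

  f_bed <- paste0(out_prefix, "_blocks.bed")
  if (nrow(blocks)) {
    bed <- data.frame(chrom = blocks$chrom, start = blocks$span_start - 1L,
                      end = blocks$span_end,
                      name = sprintf("block_%d", seq_len(nrow(blocks))))
    write.table(bed, f_bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    file.create(f_bed)
  }

  f_manifest <- paste0(out_prefix, "_manifest.json")
  mf <- c(list(package = "gecs",
               version = as.character(packageVersion("gecs")),
               fwer = thresholds$fwer,
               alpha_combined = thresholds$alpha_combined,
               alpha_by_threshold = as.list(thresholds$alpha_by_threshold),
               alpha_sma = thresholds$alpha_sma,
               n_bins_total = scan$n_bins_total,
               n_bins_naive = scan$n_bins_naive,
               n_case = scan$n_case, n_control = scan$n_control),
          manifest)
  jsonlite::write_json(mf, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(f_bins, f_blocks, f_bed, f_manifest))
}
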