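# Build a variant_panel directly from a logical carrier matrix
# (individuals x variants); positions default to the variant index.
mk_panel <- function(carriers, maf_t = 0.5, chrom = "1", pos = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(carriers))
  structure(list(maf_t = maf_t, chrom = chrom,
                 sites = data.frame(chrom = chrom, pos = as.integer(pos),
                                    id = ".", maf = 0.1,
                                    carrier_count = colSums(carriers),
                                    stringsAsFactors = FALSE),
                 carriers = carriers),
            class = "variant_panel")
}

# Random carrier matrix with no empty columns.
random_carriers <- function(N, n, density) {
  carr <- matrix(runif(N * n) < density, N, n)
  empty <- which(colSums(carr) == 0L)
  if (length(empty))
    carr[cbind(sample.int(N, length(empty), replace = TRUE), empty)] <- TRUE
  carr
}

# Carrier-set string keys of a scan_chromosome result (keep_carriers = TRUE).
emitted_keys <- function(bins) {
  vapply(seq_len(nrow(bins)),
         function(k) paste(which(bin_carriers(bins, k)), collapse = ","),
         character(1L))
}

# The canonical 4-variant worked example: carriers {1}, {1}, {2}, {3,4} of
# N = 4 individuals.
toy_panel <- function() {
  carr <- matrix(FALSE, 4, 4)
  carr[1, 1] <- TRUE; carr[1, 2] <- TRUE; carr[2, 3] <- TRUE
  carr[3:4, 4] <- TRUE
  mk_panel(carr)
}

# Write a small VCF fixture; gt is a character matrix (variants x samples).
write_vcf_fixture <- function(path, chrom, pos, ref, alt, gt, samples) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", sep = "\t")
  body <- paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  path
}
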