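# Genotype and phenotype input, minor-allele orientation, MAF filtering,
# and carrier-set panel construction.

#' Read a multi-sample VCF into a dosage table
#'
#' Reads biallelic diploid sites from a VCF (plain or bgzipped) into a
#' variant-major matrix of ALT-allele dosages (0/1/2, `NA` for missing).
#' Multiallelic records are skipped with a warning. Dosages count ALT alleles;
#' minor-allele orientation happens later in [build_panels()].
#'
#' @param path path to a VCF file with GT fields.
#' @param samples optional character vector restricting (and ordering) the
#'   sample subset; unknown names are an error.
#' @return list of class `gecs_genotypes` with elements
#'   `dosage` (variants x individuals integer matrix),
#'   `sites` (data.frame: chrom, pos, id, ref, alt),
#'   `samples` (character vector).
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))   # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(v@gt) == 0L || ncol(v@gt) < 2L) stop("VCF has no genotype columns")
  if (!all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])))
    stop("VCF records without a GT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  all_samples <- colnames(gt)
  if (!is.null(samples)) {
    missing <- setdiff(samples, all_samples)
    if (length(missing))
      stop("samples not present in VCF: ", paste(missing, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  } else {
    samples <- all_samples
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(gt) == 0L) stop("no biallelic records in VCF")
  # decode "0/1", "1|1", "./." etc. into ALT dosage
  alleles <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  idx <- match(alleles, names(known))
  dos[] <- known[idx]
  bad <- !is.na(alleles) & is.na(idx) & !alleles %in% c("./.", ".", ".|.")
  if (any(bad)) stop("unparseable GT value(s), e.g. ", alleles[which(bad)[1L]])
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  sites$id[is.na(sites$id)] <- "."
  structure(list(dosage = dos, sites = sites, samples = samples),
            class = "gecs_genotypes")
}

#' Read a phenotype table aligned to the genotype sample order
#'
#' Two-column delimited text (sample id, status 0/1), header optional.
#' Every genotyped sample must appear exactly once; rows are reordered to the
#' genotype sample order.
#'
#' @param path path to the phenotype file (whitespace/tab delimited).
#' @param sample_order character vector of genotyped sample ids, in genotype
#'   column order.
#' @return a [phenotype()] object.
#' @export
read_phenotype <- function(path, sample_order) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("phenotype file needs two columns (id, status)")
  # tolerate a header line
  if (!tab[1L, 2L] %in% c("0", "1")) tab <- tab[-1L, , drop = FALSE]
  ids <- tab[[1L]]
  status <- tab[[2L]]
  bad <- !status %in% c("0", "1")
  if (any(bad))
    stop("unknown status code(s) for: ", paste(ids[bad], collapse = ", "))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  missing <- setdiff(sample_order, ids)
  if (length(missing))
    stop("phenotype missing for sample(s): ", paste(missing, collapse = ", "))
  phenotype(as.integer(status)[match(sample_order, ids)])
}

# Minor-allele orientation and MAF for one genotype table.
# Returns list(maf, minor_is_alt) over sites; maf is NA for sites with no
# observed alleles.
site_maf <- function(dosage) {
  non_missing <- rowSums(!is.na(dosage))
  alt_count <- rowSums(dosage, na.rm = TRUE)
  alt_freq <- ifelse(non_missing > 0, alt_count / (2 * non_missing), NA_real_)
  minor_is_alt <- !is.na(alt_freq) & alt_freq <= 0.5  # tie at 0.5: ALT is minor
  maf <- ifelse(minor_is_alt, alt_freq, 1 - alt_freq)
  list(maf = maf, minor_is_alt = minor_is_alt)
}

#' Build per-chromosome carrier-set panels at one or more MAF thresholds
#'
#' Orients each site to its minor allele (sample frequency <= 0.5 over all
#' non-missing alleles of cases and controls combined; a tie at exactly 0.5
#' keeps ALT as minor), drops monomorphic sites and sites with MAF above the
#' threshold (retention is inclusive, MAF <= threshold), and records for each
#' retained site the carrier set: individuals with at least one minor allele
#' (missing genotypes count as non-carriers).
#'
#' MAF is computed on cases and controls combined and is therefore invariant
#' under phenotype-label permutation, which the permutation engine relies on.
#'
#' @param genotypes a `gecs_genotypes` object from [read_vcf()] or the
#'   simulator.
#' @param maf_t numeric vector of MAF thresholds in (0, 0.5].
#' @return list of `variant_panel` objects (one per chromosome x threshold,
#'   empty panels dropped), each with fields `maf_t`, `chrom`, `sites`
#'   (data.frame chrom/pos/id/maf/carrier_count) and `carriers`
#'   (individuals x sites logical matrix).
#' @export
build_panels <- function(genotypes, maf_t = c(0.01, 0.03, 0.05)) {
  stopifnot(inherits(genotypes, "gecs_genotypes"))
  if (any(maf_t <= 0 | maf_t > 0.5)) stop("maf_t must be in (0, 0.5]")
  o <- site_maf(genotypes$dosage)
  # carrier of >= 1 minor allele; missing -> non-carrier
  carrier_all <- matrix(FALSE, nrow(genotypes$dosage), ncol(genotypes$dosage))
  ia <- which(o$minor_is_alt)
  im <- which(!o$minor_is_alt & !is.na(o$maf))
  carrier_all[ia, ] <- !is.na(genotypes$dosage[ia, , drop = FALSE]) &
    genotypes$dosage[ia, , drop = FALSE] >= 1L
  carrier_all[im, ] <- !is.na(genotypes$dosage[im, , drop = FALSE]) &
    genotypes$dosage[im, , drop = FALSE] <= 1L
  panels <- list()
  chroms <- unique(genotypes$sites$chrom)
  for (tt in maf_t) {
    keep <- !is.na(o$maf) & o$maf > 0 & o$maf <= tt
    for (ch in chroms) {
      sel <- which(keep & genotypes$sites$chrom == ch)
      if (!length(sel)) next
      sel <- sel[order(genotypes$sites$pos[sel])]  # stable: ties keep input order
      sites <- data.frame(chrom = ch, pos = genotypes$sites$pos[sel],
                          id = genotypes$sites$id[sel], maf = o$maf[sel],
                          carrier_count = rowSums(carrier_all[sel, , drop = FALSE]),
                          stringsAsFactors = FALSE)
      panels[[length(panels) + 1L]] <- structure(
        list(maf_t = tt, chrom = ch, sites = sites,
             carriers = t(carrier_all[sel, , drop = FALSE])),
        class = "variant_panel")
    }
  }
  if (!length(panels))
    message("no variants pass any MAF threshold; returning empty panel list")
  panels
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("Variant panel: chrom %s, MAF_T = %g, %d sites, N = %d\n",
              x$chrom, x$maf_t, nrow(x$sites), nrow(x$carriers)))
  invisible(x)
}

#' Write genotypes to a minimal plain-text VCF
#'
#' Emits a VCF 4.2 file with GT-only FORMAT, suitable for round-tripping
#' simulated studies through [read_vcf()].
#'
#' @param genotypes a `gecs_genotypes` object.
#' @param path output path (plain text).
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "gecs_genotypes"))
  s <- genotypes$sites
  gt <- matrix(".\\.", nrow(genotypes$dosage), ncol(genotypes$dosage))
  gt[] <- c("0/0", "0/1", "1/1")[genotypes$dosage + 1L]
  gt[is.na(genotypes$dosage)] <- "./."
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", genotypes$samples), collapse = "\t"))
  body <- paste(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  body <- paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a phenotype table
#'
#' @param phenotype a [phenotype()] object.
#' @param samples sample ids in phenotype order.
#' @param path output path (TSV: sample_id, status).
#' @export
write_phenotype <- function(phenotype, samples, path) {
  stopifnot(inherits(phenotype, "gecs_phenotype"),
            length(samples) == length(phenotype$labels))
  writeLines(paste(samples, phenotype$labels, sep = "\t"), path)
  invisible(path)
}
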