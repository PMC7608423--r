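Package: gecs
Title: Genomic Exhaustive Collapsing Scan for Rare-Variant Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive region-based rare-variant association scanning for
    case-control studies. Enumerates every locally distinct contiguous bin of
    rare variants on a chromosome using a carrier-set pruning algorithm,
    evaluates the collapsing (COLL) chi-square test on each bin, and controls
    the family-wise error rate with empirical thresholds derived from the
    permutation distribution of genome-wide minimum p values. Includes a
    single-marker-analysis comparator, a synthetic case-control study
    simulator (neutral allele-frequency spectrum, logistic disease model) for
    threshold calibration and power studies, block merging of overlapping
    significant bins, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
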