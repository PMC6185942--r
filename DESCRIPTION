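Package: epibit
Title: Exhaustive SNP-SNP Interaction Search with Biologically Plausible
    Genotype Patterns and Bit-Packed Lookup Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exhaustive second-order SNP-SNP interaction scanning for
    case-control genome-wide association studies. Eight biologically
    plausible genotype interaction patterns, derived from a two-site
    bio-molecule complex model, collapse each SNP pair's 3x3 joint-genotype
    table into a 2x2 case/control contingency table that is scored by a
    1-d.f. Pearson chi-square test, an odds ratio and an improvement metric
    relating the pairwise p-value to the single-SNP p-values. Contingency
    tables are counted either naively or through a pre-computed lookup table
    over 2-bit-packed genotype words, which accelerates the scan by an order
    of magnitude. The package also provides PLINK text and TSV genotype
    input/output, a penetrance-calibrated case-control simulator with a
    planted pattern interaction at a stated heritability and prevalence, and
    nearest-gene network inference from top-ranked interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
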