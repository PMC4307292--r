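Package: hapblockr
Title: Diversity-Based Haplotype Block Partitioning and TagSNP Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions phased biallelic haplotype matrices into blocks of
    low haplotype diversity and selects minimal tagSNP sets per block. The
    diversity of a marker interval is the fraction of unambiguous haplotypes
    that are singletons (delta = S/U = 1 - C/U); blocks are regions with
    delta below a limit D, equivalently with common-haplotype coverage of at
    least alpha = 1 - D. A good-partner preprocessing step finds, for every
    locus, the leftmost feasible block start, after which dynamic programming
    solves both the longest-k-blocks problem and the minimum-number-of-blocks
    full segmentation. TagSNPs are chosen as the lexicographically first
    minimum-cardinality locus subset whose joint allele patterns distinguish
    all common-haplotype groups in a block. Interval scoring supports a
    chunked map/reduce decomposition executed on an in-process worker pool
    with results identical to the sequential path. Includes readers for
    HapMap3 phased-haplotype text, plain 0/1/? allele matrices and phased
    VCF, a block-structured haplotype simulator with known ground truth, and
    BED/TSV block reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    vcfR,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
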