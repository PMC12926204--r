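Package: fusionscape
Title: Windowed Phylogenomic and Epigenomic Analysis of Chromosomal
    Fusion Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for studying chromosomal fusion sites in
    great apes: multispecies-coalescent simulation of orthologous sequence
    windows, per-window HKY maximum-likelihood gene-tree classification and
    breakpoint-polarized incomplete-lineage-sorting profiles, windowed
    nucleotide diversity and Tajima's D from first principles, segmental
    duplication copy counting and flank-based orthology, subterminal
    satellite and spacer architecture statistics, centromere-dip-region
    calling from methylation tracks, structural haplotype classification,
    and singly unique nucleotide k-mer (SUNK) presence analysis.  A
    synthetic-data module generates every input class with the statistical
    structure the analyses assume, so the whole pipeline is exercisable and
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
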