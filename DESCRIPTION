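Package: satmine
Title: Mining and Evolutionary Analysis of Tandem Satellite Repeats in
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Genome-wide annotation and evolutionary analysis of tandemly
    repeated satellite DNA families such as the subtelomeric khipu repeat
    of common bean. Builds a position-specific scoring profile from a seed
    monomer alignment, scans assemblies on both strands for monomer units,
    applies tandem-block terminal/length/ambiguity filters and a
    per-pseudomolecule naming scheme, localises centromeres from
    centromeric satellites and assigns short-arm/centromere/long-arm
    codes, screens monomers for recombination by triplet maximum
    chi-square scanning, reconstructs a neighbor-joining phylogeny under
    Jukes-Cantor distances with bootstrap support, cross-tabulates clades
    against chromosomal locations to quantify interchromosomal spreading
    and local duplication, compares independently sequenced contigs
    against the assembly for quality control, and simulates genomes with
    planted satellite arrays and full ground truth so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
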