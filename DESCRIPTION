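Package: matriline
Title: Maternal Lineage Analysis of Pedigrees with Mitochondrial Haplotype Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for matrilineal pedigree analysis when mitochondrial DNA
    haplotypes are known for part of a population. Provides pedigree parsing,
    validation and auto-correction; detection of haplotype conflicts along
    maternal lines with pedigree-reliability indices (HC, IC, MISPLACED and a
    pruned conflict count); line-wide haplotype imputation; effective
    population sizes of maternal, mtDNA-haplotype and paternal lines from the
    probability of identity in founder and reference populations; and an
    optimized molecular-sampling planner that spreads a sequencing budget
    across maternal lines and picks maximally dispersed individuals within
    each line. A seeded synthetic-pedigree simulator with ground truth
    supports testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
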