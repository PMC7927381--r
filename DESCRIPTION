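Package: radpanels
Title: Two-Pipeline RAD-Seq SNP Panel Comparison and Population Genomics
Version: 0.1.0
Authors@R:
    person("Aran", "Beade", email = "aran.beade@posteo.net",
           role = c("aut", "cre"))
Description: Simulation, filtering, reconciliation and comparison of SNP
    panels produced by two de novo RAD-seq building-loci pipelines. Includes
    a structured-population genotype/read-depth simulator with two emulated
    genotype callers, the seven-step SNP filtering cascade (biallelic,
    minimum coverage, SNPs per locus, minimum allele count, per-population
    call rate, Hardy-Weinberg, one SNP per locus) with audit trails, greedy
    Hamming-threshold clustering of tag catalogues into shared and private
    RAD loci, common/merged panel construction, genotype concordance
    classification with missing-data source attribution, and
    population-genomic statistics (observed/expected heterozygosity, FIS
    with bootstrap confidence intervals, global Weir-Cockerham FST, rarefied
    allelic richness, Hardy-Weinberg exact tests) implemented from standard
    formulas. GENEPOP, FASTA and TSV interfaces plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
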