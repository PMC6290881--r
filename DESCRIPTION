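Package: varcascade
Title: Family-Based Rare-Variant Prioritisation and Case-Control
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritises rare, protein-altering candidate variants in
    multiplex disease pedigrees under a dominant model: a shared-heterozygote
    filter over whole-exome-sequenced affected relatives, consequence and
    population-frequency screens, and a cross-family gene recurrence step.
    Tabulates co-segregation of candidate variants with affection status in
    extended pedigrees, accounting for incomplete penetrance, phenocopies and
    married-in individuals.  Implements the downstream case-control analysis:
    allelic association tests (chi-square with optional Yates continuity
    correction, Fisher exact), odds ratios with Woolf confidence intervals
    and Haldane-Anscombe zero-cell correction, an exact conditional
    Hardy-Weinberg equilibrium test, Bonferroni correction, and a cumulative
    carrier (burden) analysis pooling several rare variants.  A seeded
    synthetic-data generator (pedigree simulation, Mendelian gene dropping,
    penetrance/phenocopy phenotype assignment, case-control cohort counts)
    supports end-to-end validation without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
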