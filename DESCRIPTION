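Package: surfline
Title: Detecting the Genetic Signature of Range Expansions from Georeferenced Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the genetic signature of a range expansion (serial
    founder effects and allele surfing) from georeferenced multiallelic
    diploid genotypes. Provides GENEPOP and delimited-table genotype I/O
    with call-rate filtering, grid-cell quality control (Monte-Carlo
    Hardy-Weinberg exact tests, genotypic linkage-disequilibrium
    permutation tests, null-allele estimation), projection of samples onto
    an invasion-path polyline with equidistant grouping, diversity
    statistics (rarefied allelic richness, unbiased expected
    heterozygosity, private alleles, Nei's GST, Weir-Cockerham FST),
    Mantel permutation tests of diversity gradients and per-allele
    frequency clines with Bonferroni correction, a serial-founder
    stepping-stone simulator of microsatellite-like data with ground
    truth, and a pipeline orchestrating the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    geosphere,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
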