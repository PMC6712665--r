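Package: emgekit
Title: Discovery, Host Assignment and Quantification of Extrachromosomal
    Mobile Genetic Elements from Long-Read Metagenome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-assembly analysis of plasmids and bacteriophages
    (extrachromosomal mobile genetic elements, eMGEs) in gut metagenomes.
    Recovers circular contigs from a unitig assembly graph using external
    binning information, classifies them as plasmids or phages from
    gene-level evidence, detects terminal direct repeats to distinguish
    misassembled linear phage genomes from true circles and linearizes
    them, predicts eMGE hosts by abundance co-occurrence, CRISPR
    spacer-protospacer matching and DNA methylation motif (IPD) profiles,
    clusters and quantifies eMGEs across samples with a
    plasmid-per-chromosome ratio estimator, and tests plasmid-versus-
    chromosome functional (COG) enrichment. Ships a synthetic-community
    generator that emulates host chromosomes carrying circular plasmids
    and linear phages with terminal direct repeats, long reads,
    methylation kinetics, CRISPR arrays and coupled cross-sample
    abundances, with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
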