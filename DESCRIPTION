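Package: oriturn
Title: Replication Origin Calling and Evolutionary Turnover Analysis for
    SNS-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of DNA replication origins
    mapped by short nascent strand sequencing (SNS-seq). Detects origins as
    windows of significant read enrichment with controlled error rate,
    localizes initiation peaks by kernel smoothing, profiles nucleotide
    composition, GC/AT skew and G-quadruplex motifs around peaks, quantifies
    purifying selection from derived-allele-frequency stratified SNP
    densities, clusters genomic background composition from k-mer counts via
    non-negative matrix factorization and k-means, and measures cross-species
    functional conservation of origins against randomization nulls. Includes
    a fully seeded synthetic-data generator (genomes, read tracks, variant
    tables, homology maps) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
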