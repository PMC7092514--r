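Package: spliceScape
Title: Alternative-Splicing Landscape Analysis from Percent-Spliced-In Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of bulk RNA-seq alternative-splicing
    quantifications for multi-tissue, two-sex, two-treatment designs such as
    the hypothalamic-pituitary-gonadal (HPG) axis under restraint stress.
    Reads per-sample percent-spliced-in (PSI) tables in a Whippet-compatible
    dialect, computes replicate-bootstrap delta-PSI significance calls,
    tallies splicing events by type with chi-square tests against uniform and
    genome-derived nulls, classifies events into 5'UTR/CDS/3'UTR transcript
    regions from GFF3 annotation, compares spliced-exon length distributions
    to the genomic distribution, abstracts Gene Ontology annotations of
    spliced genes to parent terms and tests deviation from genomic
    expectation, translates spliced exons phase- and strand-aware, detects
    group-exclusive isoforms from TPM tables, and ships a seeded synthetic
    data generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
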