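Package: ovamir
Title: Two-Library Small RNA-Seq miRNA Profiling with Exact-Test
    Differential Expression and qPCR Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for two-library small RNA sequencing
    studies of miRNA expression: FASTQ cleaning and collapsing to unique
    tags, hierarchical exact-match annotation against a reference bundle
    (mature/star miRNAs, hairpins, ncRNA classes, genome), reads-per-million
    normalization, the Audic-Claverie exact test for two-library
    differential expression with zero imputation and low-expression
    filtering, and qRT-PCR relative quantification by the 2^-ddCt method
    with one-way ANOVA and Duncan's multiple range test. Includes a
    synthetic-data generator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
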