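Package: fastaforge
Title: FASTA Dataset Construction, Conserved-Gene Annotation and
    Convention-Based Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building and transforming FASTA sequence datasets
    from the command line or from R. Provides a tolerant FASTA reader and
    strict writer (plain or gzip), a family of filtering, sorting and
    editing operations, reproducible JSON parameter files, a self-contained
    conserved-gene annotation pipeline (open reading frame discovery,
    Smith-Waterman protein search with Karlin-Altschul E-values, exon
    sorting and iterative exon joining across canonical GT-AG splice
    sites, CDS prediction), a convention-based workflow engine for chaining
    commands over a directory workspace, man-page generation, and
    deterministic synthetic-data generators used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
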