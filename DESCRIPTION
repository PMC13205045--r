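Package: mitoPanels
Title: Cell-Type Marker Panels and Lineage Tracing from Single-Cell
    Mitochondrial DNA SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Defines cell types and traces cell lineages from single-cell
    mitochondrial DNA variation. Converts per-cell mitochondrial allele
    counts (MAESTER- or mtscATAC-style sparse base-count matrices) into
    binary SNP presence/absence calls, discovers panels of unique
    three-SNP combinations that collectively mark a target cell class
    while being absent from every other cell of the same individual,
    orders and clusters cells by shared SNPs for clonal-structure
    heatmaps, and matches reference panels against a second sample (for
    example pre- versus post-hepatectomy liver) to identify putative
    descendants. Includes a forward simulator of mitochondrial
    heteroplasmy drift along a cell-division tree with a sequencing
    readout, so the whole pipeline is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
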