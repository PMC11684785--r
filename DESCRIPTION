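Package: clonepick
Title: Rational Selection of T Cell Receptor Clones from Paired
    Single-Cell Expression and V(D)J Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for choosing a T cell receptor (TCR) clone for
    transgenesis from polyclonal responders profiled by paired single-cell
    RNA sequencing and V(D)J repertoire sequencing.  Ingests 10x-style
    expression matrices and contig annotations (10x CSV or AIRR TSV),
    performs median-absolute-deviation based cell quality control,
    normalisation, clustering and embedding, resolves per-cell alpha/beta
    chain pairs and calls clonotypes, links clonotypes to phenotype,
    quantifies clonal expansion and repertoire diversity, gates clonotypes
    on activation and memory markers, ranks candidates, and exports the
    selected clonotype's TRA/TRB consensus sequences ready for gene
    synthesis.  Includes a synthetic data generator that emulates sorted
    tetramer-positive, tetramer-negative and naive CD8 T cell samples with
    planted expanded clones, phenotype programs and quality-control
    outliers, so the whole pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    RANN,
    cluster,
    Biostrings,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    tools,
    methods
Suggests:
    uwot,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
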