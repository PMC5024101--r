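Package: linctools
Title: Discovery, Expression Profiling, Functional Annotation and miRNA
    Interaction Screening of Long Intergenic Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for genome-wide identification of long
    intergenic non-coding RNAs (lincRNAs) from assembled transcriptomes. It
    implements a filter cascade (intergenic class code, transcript length,
    open reading frame length, protein and domain homology evidence, coding
    potential, proximity to coding genes) with full per-stage accounting,
    tissue-specificity scoring (the tau index) and expression classification
    across multi-tissue FPKM matrices, GO annotation transfer to lincRNAs by
    global label propagation over a bicolor co-expression/protein-interaction
    network, hypergeometric GO enrichment, and plant-style miRNA target
    scanning with an additive complementarity expectation score. A seeded
    synthetic-data generator plants ground truth for every stage so the whole
    pipeline can be exercised and validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    BiocGenerics,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
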