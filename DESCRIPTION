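Package: wgacnv
Title: Copy Number Variant Detection from Low-Coverage Single-Cell
    Whole-Genome-Amplified Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A window-based pipeline for detecting chromosomal copy number
    variants in low-coverage single-end sequencing of whole-genome-amplified
    (WGA) single cells: fixed-size genomic window grids with GC/N annotation,
    filtered per-window read counting from BAM, GC correction by locally
    weighted regression, normalization against a matched euploid control,
    MAPD and coverage-uniformity quality control, circular binary
    segmentation with permutation significance, threshold-based gain/loss
    calling with karyotype-style reporting, and concordance scoring against
    confirmed karyotypes. Includes a per-window count simulator emulating the
    amplification-noise profiles of common WGA chemistries (MALBAC, PicoPLEX,
    GenomePlex, MDA) with calibration routines tying simulator dispersion to
    target MAPD and repeat-correlation values, so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    IRanges,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    Rsamtools,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
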