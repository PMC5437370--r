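Package: barcodeval
Title: Chloroplast Marker Discovery and Multi-Method DNA Barcode Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative chloroplast-genome marker discovery and
    for evaluating candidate DNA barcodes with four complementary
    species-discrimination methods. Includes quadripartite plastome
    partitioning, exact repeat scanning, conserved-flank primer window
    selection, alignment cleaning with simple indel coding, nucleotide
    diversity and deletion-insertion polymorphism statistics, p-distance
    matrices with barcode-gap assessment and ABGD-style partitioning,
    leave-self-out top-hit classification, diagnostic-character logic
    formula induction, neighbor-joining trees with bootstrap monophyly
    scoring, exhaustive marker-combination evaluation, and a seeded
    synthetic multi-species dataset generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
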