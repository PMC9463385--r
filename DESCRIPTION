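Package: actiondown
Title: Actionability Annotation and In Silico Panel Down-Sampling for
    Somatic Cancer Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates somatic cancer alterations (SNVs/indels, copy-number
    segments, structural variants) against a biomarker-drug knowledge base,
    classifies matches into on-label and off-label repurposing categories by
    evidence tier, and compares sequencing platforms by restricting
    whole-genome calls to exome, comprehensive-panel and hotspot-panel
    footprints in silico. Includes tumour mutation burden estimation with
    fixed platform denominators, chi-square microsatellite instability
    scoring from tumour/normal repeat-length distributions, and a synthetic
    cohort generator with ground-truth labels so every stage is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
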