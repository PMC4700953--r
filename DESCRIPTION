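Package: sweepscan
Title: Two-Step Genome Scans for Positive Selection in Replicated
    Chicken Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects footprints of positive selection from whole-genome
    variant data of replicated domestic chicken populations using two
    complementary screens: parallel fixation of the same allele across
    independently bred layer and broiler populations (windowed allele
    frequency elevated in all populations), and parallel divergence
    between the layer and broiler groups (windowed Weir-Cockerham Fst
    thresholded at the empirical top percentile), with supporting
    integrated haplotype score (iHS) and expected heterozygosity tracks.
    Includes VCF and pooled allele-count ingestion with quality and
    read-depth filters, a 40 kb / 5 kb overlapping-window frame, region
    merging with empirical percentile P values, and a Balding-Nichols
    synthetic-data generator with implantable hard sweeps so the whole
    pipeline is testable without access to commercial sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
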