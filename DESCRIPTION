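Package: earnorm
Title: Expressed Alu Repeat Normalization for RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relative quantification and normalization of RT-qPCR
    data using expressed Alu repeats (EAR) as a universal reference signal,
    alongside the classic GeNorm reference-gene stability workflow.
    Includes standard-curve calibration with amplification-efficiency
    estimation, technical-replicate aggregation and efficiency-corrected
    relative quantities, pairwise-variation gene stability (M) with stepwise
    exclusion and geometric-mean normalization factors, melt-curve quality
    control with peak calling and replicate concordance, in-silico PCR primer
    validation, the nonparametric comparison statistics used to contrast
    normalization strategies, and a seeded simulator of quantification-cycle
    experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    utils,
    BiocGenerics,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
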