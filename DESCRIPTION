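Package: zknock
Title: Knockoff Inference for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Summary-statistics knockoff inference for genome-wide association
    studies. Generates knockoff copies of GWAS Z-scores directly from an LD
    matrix (no individual-level genotypes needed), applies the multiple-knockoff
    filter for false discovery rate control, and supports meta-analysis of
    several studies with arbitrary sample overlap via an estimated study
    correlation matrix, optimal study weights and a dependency factor that
    inflates the knockoff noise. Includes LD estimation from a reference panel
    (VCF or PLINK), tight-LD pruning by hierarchical clustering, genome block
    partitioning, and a synthetic cohort simulator for power/FDR experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
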