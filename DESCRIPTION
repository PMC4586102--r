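Package: semscan
Title: Stochastic Epigenetic Mutation Detection for DNA Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects stochastic epigenetic mutations (SEMs) in Illumina
    methylation array data as per-CpG extreme outliers beyond the Tukey
    fences Q1 - 3*IQR and Q3 + 3*IQR, and analyses the resulting per-subject
    epimutation burden. Includes sample and probe quality control with
    quantile normalisation and 27K/450K platform pooling, gene-level
    hypergeometric enrichment of epimutated probes, degree-of-skewing
    computation for the HUMARA X-inactivation assay, standardized
    regression and recursive path analysis with multiple imputation pooled
    by Rubin's rules, and a synthetic-cohort generator for end-to-end
    validation of the whole pipeline.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
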