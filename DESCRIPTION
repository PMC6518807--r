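Package: tmbpdl1
Title: Combined Tumor Mutational Burden and PD-L1 Biomarker Pipeline for NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for combined biomarker
    analysis in non-small cell lung cancer: paired tumor/normal somatic
    variant filtering from count-level evidence, panel-normalized tumor
    mutational burden (TMB) with data-adaptive three-class stratification,
    semiquantitative PD-L1 tumor-cell and immune-cell scoring ladders,
    combined TMB-by-PD-L1 patient classification, and the Kaplan-Meier,
    log-rank, contingency, rank-correlation and Kruskal-Wallis/Dunn
    statistics used to relate biomarker strata to overall survival and
    clinicopathological characteristics. Includes a synthetic cohort
    generator with known ground truth so every stage is testable without
    patient-level data.
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
    readr,
    rlang (>= 1.0.0),
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    GenomicRanges,
    IRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
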