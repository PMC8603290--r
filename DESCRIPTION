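Package: oncoprofile
Title: Tumor/Normal Genomic Characterization and Immunotherapy Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for desk-scale tumor/normal genomic
    characterization and immune-checkpoint-inhibitor cohort analysis. Implements
    multi-caller somatic variant consensus merging with rule-based artifact
    filtering and tumor mutation burden (TMB) counting; a tumor/normal
    log-R-ratio (LRR) copy-number caller with informative-SNP selection,
    GC-content depth adjustment and moving-window median smoothing; variance
    stabilized expression with variable-gene PCA and gene-set signature
    scoring; and cohort biomarker statistics (ROC/Youden cut-off selection,
    four-group CD8xCD155 stratification, Fisher's exact test, Kaplan-Meier
    estimation with log-rank comparison, and paired pre/post marker tests).
    A negative-binomial synthetic-data generator with known ground truth makes
    every stage testable without access-restricted sequencing data.
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
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
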