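Package: basalscreen
Title: Basal-Subtype Classification and Drug-Sensitivity Screening for HNSCC Cell Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for linking head and neck squamous cell
    carcinoma (HNSCC) molecular subtypes to drug sensitivity. Implements
    nearest-centroid transcriptomic subtype classification with consensus
    basal/non-basal calling across cell-line datasets, four-parameter logistic
    dose-response fitting with IC50 and area-under-curve descriptors, Bliss
    independence synergy scoring of two-drug dose matrices, marker selection by
    fold change and ROC AUC, moderated t-test mutation-response association,
    qPCR delta-delta-Ct quantification, and clonogenic survival fractions.
    Ships seeded synthetic-data generators that emulate every input the
    pipeline consumes, and a packaged 25-cell-line screen table for worked
    examples.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    limma,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
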