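Package: osteomir
Title: miRNA Panel Biomarker Modelling for Postmenopausal Osteoporosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to integrate a circulating microRNA (miR-194-5p) with
    routine medical-examination items into a panel biomarker for
    postmenopausal osteoporosis. Implements Spearman screening of
    examination items against lumbar-spine bone mineral density,
    radial-basis-function network regression of normalized BMD, a stacked
    derivative-feature network (DANN) built on distance-ranked cohort
    divisions, a density-peak patient-similarity network, and ROC-based
    evaluation including Youden cut-points, sensitivity at fixed
    specificity, and the DeLong paired AUC test. A seed-reproducible
    Gaussian-copula cohort simulator emulates the correlation and
    skewness structure of the study cohorts so the full pipeline is
    testable without patient data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
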