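Package: csfprm
Title: Label-Free Parallel Reaction Monitoring Analysis of CSF Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tidyverse-style pipeline for label-free parallel reaction
    monitoring (PRM) targeted proteomics of cerebrospinal fluid biomarker
    panels. Converts long-format transition (product-ion) peak-area reports
    into peptide and protein quantities; corrects injection-level signal
    drift with spiked reference peptide standards; normalizes against pooled
    global internal standard (GIS) injections per batch; reports coefficient
    of variation precision QC; regresses out age and sex; and evaluates
    candidate biomarkers by one-way ANOVA with Tukey post hoc tests and
    false-discovery-rate control, biweight midcorrelation with immunoassay
    traits, and per-protein cross-validated logistic regression ROC analysis.
    Includes a synthetic-study generator emulating a multi-batch PRM design
    with known ground truth, so every stage is testable end to end.
License: MIT
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
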