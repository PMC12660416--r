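Package: pfsratio
Title: Intra-Patient Treatment Comparisons with Progression-Free Survival Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares sequential systemic therapies within patients using the
    progression-free survival (PFS) ratio, also known as the growth modulation
    index (PFS2/PFS1). Builds consecutive-line treatment pairs from therapy
    course tables, computes ratios with right-censoring semantics, estimates
    naive and Kaplan-Meier median ratios with confidence intervals, compares
    ratio distributions between subsequent therapies with the k-sample
    log-rank test, and quantifies the PFS1-PFS2 association under censoring
    with a Gaussian-copula maximum-likelihood estimator. A configurable
    synthetic-cohort generator emulates neuroendocrine-neoplasm treatment
    sequences (correlated line-wise PFS, heavy-tailed months-scale durations,
    administrative censoring of the latest line) so the whole pipeline is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
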