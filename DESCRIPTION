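Package: pgsdeviate
Title: Classifying Individuals Who Deviate from Their Polygenic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying individuals whose measured quantitative
    phenotype is inconsistent with the value predicted by a common-variant
    polygenic score. Implements per-individual polygenic scoring from GWAS
    summary-statistic weights, phenotype residualization and rank-based
    inverse-normal transformation, additive polygenic-model cohort simulation,
    four deviator classifiers (Mahalanobis distance with chi-squared 2-df
    p-values, regression-residual z-scores, rank-matched empirical p-values,
    and centile-wise IQR fences), and follow-up enrichment statistics
    (exact odds ratios and covariate-adjusted regression models) comparing
    flagged individuals with those concordant with their score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
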