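Package: mirpanel
Title: Salivary miRNA Biomarker Panel Screening and Cross-Validated Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and validating small-RNA biomarker panels
    from miRNA-seq count data, modelled on a salivary miRNA case-control
    study design in autism spectrum disorder. Provides reads-per-million
    normalization with a detection filter, a non-parametric differential
    screen (Mann-Whitney U with Benjamini-Hochberg false-discovery control,
    Z-score differences and Cohen's d, Spearman correlations with behavior
    scores), maximum-likelihood logistic classification with ROC analysis,
    NIPALS partial least squares discriminant analysis embedded in
    Monte-Carlo cross-validation with stepwise panel sizes, hierarchical
    clustering exports, and miRNA target-set enrichment by Fisher's exact
    test. A parameterized synthetic-data generator reproduces the
    statistical structure the pipeline assumes so that every stage runs and
    is testable without access to the original sequencing cohort.
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
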