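Package: dmrpipe
Title: Methylome Variance Partitioning and Differentially Methylated Region
    Calling for Multi-Region Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for Illumina EPIC-style CpG methylation studies
    with repeated samples per donor: detection call-rate, sex and SNP-fingerprint
    quality control; beta to M-value transformation; covariate-adjusted PCA with
    per-component ANOVA variance partitioning and classical MDS; per-CpG
    differential methylation with a donor random intercept fitted by profiled
    REML, plus per-region fixed-effect models and genomic-inflation correction;
    spatially aware differentially methylated region (DMR) calling by
    Stouffer-Liptak combination of autocorrelation-adjusted p values with Sidak
    correction; and linkage of DMRs to gene expression via logCPM filtering and
    a parallel mixed model. Includes a synthetic cohort generator with ground
    truth for recovery and calibration testing.
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
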