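Package: musclemeth
Title: Long-Term Skeletal-Muscle DNA Methylation Analysis After Critical Illness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential DNA methylation analysis pipeline for Infinium
    EPIC-style beta-value matrices, built around a former-ICU-patient versus
    control muscle cohort design. Provides beta/M-value transforms, detection-p
    and SNP probe filters, stratified quantile normalisation, per-CpG
    covariate-adjusted linear models with Benjamini-Hochberg FDR control,
    probe-to-gene region annotation and differentially methylated gene
    aggregation, pathway over-representation with Wallenius noncentral
    hypergeometric probe-bias correction, methylation-expression Spearman
    correlation enrichment with two-proportion Z and Kolmogorov-Smirnov
    comparisons, directional risk-factor association models, and a seeded
    synthetic-cohort generator with ground-truth labels for validating every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
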