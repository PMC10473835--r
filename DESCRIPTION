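Package: npxcc
Title: Cross-Cohort Analysis of Olink NPX Inflammatory Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing targeted affinity proteomics (PEA/NPX) panels
    across cohorts measured on separate plate sets. Implements bridging
    normalization from pooled plasma controls, limit-of-detection and
    PCA-based quality control, covariate-adjusted differential expression
    with empirical-Bayes variance moderation and false-discovery-rate
    control, host-factor and SNP association scans, two-layer unsupervised
    clustering of food-derived metabolome and proteome profiles, and
    metabolite-protein regression matrices. Includes a synthetic two-cohort
    generator with known ground truth so every stage of the pipeline can be
    exercised and validated without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
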