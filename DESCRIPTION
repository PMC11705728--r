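Package: hicox
Title: High-Order Gene-Smoking Interaction Scans for Survival with DNA
    Methylation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-phase epigenome-wide analysis of high-order gene-smoking
    interactions on cancer survival. Provides probe- and sample-level quality
    control for DNA-methylation beta-value matrices, a histology-stratified Cox
    proportional-hazards engine with full factorial interaction expansion, a
    hill-climbing epigenome-wide interaction scan with Benjamini-Hochberg false
    discovery control and discovery/validation two-phase decision rules, the
    TRIUNE integrated risk score with quartile subgroup and Kaplan-Meier
    analyses, prognostic-model discrimination comparison via inverse
    probability of censoring weighted time-dependent ROC/AUC and the
    concordance index, methylation-expression cis-regulation follow-up, and a
    multi-center synthetic cohort generator with planted interaction signals
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
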