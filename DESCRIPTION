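Package: clonoshed
Title: Multi-Lesion Tumor Heterogeneity and Cell-Free DNA Shedding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies spatial heterogeneity of somatic mutations across
    multiple metastatic lesions and their representation in plasma
    cell-free DNA. Builds power-aware mutation presence matrices with a
    read-support rescue step, classifies mutations as truncal, branch or
    private, estimates cancer cell fractions from read counts under a
    purity/copy-number binomial model, classifies copy-number events
    relative to ploidy, annotates driver alterations, models detection
    power for circulating tumor DNA, exhaustively scores driver recovery
    over biopsy subsets, and derives ROC-based cancer-cell-fraction
    thresholds for calling mutation truncality from plasma. A synthetic
    multi-lesion cohort generator with known clonal truth exercises every
    stage without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
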