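Package: survregroup
Title: Survival-Curve Clustering for TNM Stage Regrouping in Non-Small
    Cell Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Regroups histology-specific TNM subgroups of non-small cell
    lung cancer (adenocarcinoma and squamous cell carcinoma) into modified
    stages and sub-stages by hierarchically clustering Kaplan-Meier
    survival curves under a log-rank chi-squared curve distance. Encodes
    the 8th-edition AJCC/UICC lung stage grouping and a published modified
    grouping, compares staging systems by adjacent-stage Cox hazard
    ratios, Harrell's concordance index with bootstrap confidence
    intervals, and bootstrap calibration of 3- and 5-year cancer-specific
    survival, and ships a calibrated SEER-like synthetic cohort generator
    so the whole pipeline is testable without registry access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
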