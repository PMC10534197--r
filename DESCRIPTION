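Package: cetaclock
Title: Epigenetic Age Clocks for Cetaceans from Methylation Beta Values
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds, validates, and applies epigenetic age clocks from
    DNA methylation beta-value matrices. Implements detection p-value
    CpG filtering, elastic-net clock training with internally
    cross-validated penalty selection over an alpha grid, leave-one-out
    cross-validation, logistic confounder screening, multi-species joint
    training-set merging, and population age-structure comparison with
    exact Wilcoxon tests. Ships the published eight-CpG Maui/Hector's
    dolphin clock as a directly applicable scoring function, and a
    synthetic methylation data generator so the entire pipeline is
    testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
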