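Package: mdrer
Title: Multifactor Dimensionality Reduction for Imbalanced Case-Control Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene-gene interactions (epistasis) in case-control SNP
    data with multifactor dimensionality reduction (MDR). Alongside the
    classic case:control ratio classifier and raw misclassification error,
    it implements a percentage-ratio risk classifier and the balanced
    classification error (the MDR-E and MDR-ER variants), which correct the
    systematic low-risk bias MDR exhibits when controls heavily outnumber
    cases. Includes exhaustive n-locus search with 10-fold cross-validation
    and cross-validation consistency model selection, contingency statistics
    (sensitivity, specificity, balanced accuracy, Woolf odds-ratio
    intervals, chi-square tests), a penetrance-model synthetic genotype
    generator for imbalanced designs, under-sampling utilities, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
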