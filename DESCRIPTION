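Package: gllrm
Title: Graphical Log-Linear Rasch Models for Polytomous Item Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Conditional maximum likelihood estimation of polytomous
    (partial-credit) Rasch models and their graphical log-linear
    extensions with uniform local dependence and uniform differential
    item functioning (DIF).  Includes the item-analysis battery used in
    patient-reported outcome validation: Andersen conditional
    likelihood ratio tests, item-restscore fit statistics, conditional
    partial Goodman-Kruskal gamma tests of local dependence and DIF,
    Kelderman confirmatory likelihood ratio tests, a Monte-Carlo
    unidimensionality test, Benjamini-Hochberg multiplicity adjustment,
    Monte-Carlo reliability, targeting indices, DIF-equated scores, an
    iterative model-search strategy, and a synthetic questionnaire data
    generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
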