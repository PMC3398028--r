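Package: pvmine
Title: Association Rule Mining and Disproportionality Analysis for
    Adverse Drug Event Signal Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating signal-detection algorithms on
    spontaneous reporting system (SRS) data. Provides a Monte Carlo
    simulator of drug-adverse-event report grids with planted true
    signals under a Poisson reporting model, an association-rule miner
    with support/confidence/lift thresholds and drug-to-ADE template
    matching, the standard disproportionality statistics (PRR, ROR,
    BCPNN information component, MHRA composite criterion), and an
    evaluation harness computing sensitivity/specificity sweeps, ROC
    curves and AUC against the planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
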