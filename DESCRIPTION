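Package: beadtitration
Title: Bead-Level Dilution Analysis for Illumina BeadArray Titration
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-source RNA titration (dilution)
    experiments on the Illumina BeadArray platform at the bead level.
    Provides a ground-truthed simulator of bead-level data across
    mixture proportions and starting-RNA quantities, bead-level
    preprocessing (median/MAD outlier removal, per-section
    summarisation, empirical detection p-values from negative
    controls, within-quantity quantile normalisation, analysis-group
    filtering), a weighted non-linear dilution model fitted per
    bead-type with a Wald test for differential expression,
    signal-to-noise and sample-size inflation summaries,
    detection/differential-expression concordance between starting
    quantities, and cross-quantity normalisation strategies (quantile
    mapping and locally smooth bias correction) with squared-error
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
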