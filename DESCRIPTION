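Package: phewasKit
Title: Mass Univariate PheWAS Regression Engine for Longitudinal EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Transforms longitudinal ICD-coded electronic health records and
    group demographics into per-patient PheCode feature matrices (binary,
    count, and duration aggregation), runs covariate diagnostics and mass
    univariate phenome-wide association (PheWAS) regressions with the target
    variable as dependent or predictor, applies Bonferroni and
    Benjamini-Hochberg multiple-comparison correction, and emits volcano,
    effect-size and sorted-table result artifacts. Includes case definition
    by ICD record-count thresholds, one-to-one matched-control selection,
    and a seeded synthetic-EHR generator with configurable injected
    PheCode-target effect sizes so that every stage is testable without
    access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
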