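Package: normascan
Title: Normative Modeling and Anomaly Detection for Regional Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds per-metric polynomial normative age models from a
    healthy-control cohort of regional brain-morphometry measurements
    (Desikan-Killiany cortical thickness and grey-matter volumes,
    subcortical volumes, asymmetry indices), scores individual scans as
    signed log10(p) anomaly maps against those models, cleans the
    normative cohort by subject-wise leave-one-out cross-validation, and
    summarises anomaly patterns across groups (percentage maps, Cohen's d,
    normalized L2 map distances, ROC). Includes a synthetic-cohort
    generator so the full pipeline is exercisable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
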