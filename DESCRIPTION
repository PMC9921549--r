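Package: antioxsar
Title: Multi-Assay Antioxidant Structure-Activity Relationship Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mechanism-based antioxidant quantitative
    structure-activity relationship (QSAR) analysis across multiple
    radical-scavenging assays (ORAC, SOAC, MTT, ABTS, DPPH). Computes the
    five reaction-mechanism enthalpies (BDE, IP, PDE, PA, ETE) that govern
    hydrogen-atom transfer, single-electron transfer followed by proton
    transfer, and sequential proton-loss electron-transfer pathways from
    species formation enthalpies; assembles continuous molecular-descriptor
    tables through a pluggable provider backed by OpenBabel; reduces the
    candidate pool with a filter cascade (constant drop, pairwise
    correlation filter, local-descriptor exclusion, partial-correlation
    screen from the precision matrix) intersected across datasets; trains
    and evaluates gradient-boosted tree models with MAE/STD and
    binary-cross-entropy metrics and min-max-scaled key-feature
    importances; and embeds all compounds jointly into a two-dimensional
    chemical space after standardization. A synthetic-data generator with
    exactly controlled empirical correlation structure makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    yaml,
    xgboost,
    uwot,
    ggplot2,
    cluster,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB
Config/testthat/edition: 3
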