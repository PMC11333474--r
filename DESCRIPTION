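Package: comboscreen
Title: Drug-Combination Screening Analysis with DSS Scoring, Loewe Synergy
    and Adapted RECIST Response Classification
Version: 0.1.0
Authors@R:
    person("Screen", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable analysis pipeline for high-throughput drug and
    drug-combination viability screens. Normalizes plate-reader signals to
    percent inhibition against on-plate controls, fits asymmetric (5PL)
    logistic dose-response curves with absolute IC50 estimation, computes
    drug sensitivity scores (DSS) and differential combination scores
    (dcDSS) with hit calling and hierarchical clustering of response
    profiles, evaluates two-drug synergy against the Loewe additivity
    reference for 5x5 checkerboard matrices and fixed-ratio ray designs
    (interaction indices with bootstrap confidence intervals), and
    classifies xenograft tumour responses with RECIST criteria adapted to
    zebrafish embryo models. Includes seeded synthetic-data generators
    emulating every assay design so the full pipeline runs with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
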