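Package: fluxshift
Title: Predicting Drug-Induced Metabolic Flux Redistribution from Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constraint-based pipeline for predicting how a perturbation
    (e.g. a drug treatment) redistributes metabolic flux in a cell.
    Builds condition-specific metabolic models from gene expression,
    medium composition and measured respiration rates; estimates a
    reference flux distribution by expression-weighted flux minimization
    followed by artificially-centered hit-and-run sampling of the
    near-optimal solution space; and fits a perturbed flux state to
    differential-expression fold changes with a quadratic metabolic
    transformation algorithm (qMTA). Includes a synthetic-data generator
    producing toy networks with known ground-truth flux shifts so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    quadprog,
    stats,
    utils,
    tools,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
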