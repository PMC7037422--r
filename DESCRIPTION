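Package: nanorad
Title: Synergy Analysis of Nanomaterial and Ionizing Radiation Co-Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify whether metal-oxide nanomaterials sensitize
    cells to ionizing radiation. Implements flow-cytometry side-scatter
    gating for particle internalization, live/apoptotic/dead classification
    from DiOC6(3) and propidium iodide intensities, four-parameter
    log-logistic (LL4) dose-response modelling, an independent-action
    (Bliss) null model for the combined nanomaterial-plus-radiation
    response, a coefficient-distance synergy score, automated nucleus
    counting for growth curves, and 2^-ddCt relative quantification for
    qPCR stress markers. Includes a seeded synthetic-data generator that
    emulates the statistical structure of the assays for validation and
    power studies, and a file-based pipeline orchestrating the full
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
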