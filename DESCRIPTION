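Package: spheroflux
Title: Extracellular Flux Analysis of Single Cancer Spheroids
Version: 0.1.0
Authors@R:
    person("Spheroflux", "Developers", email = "spheroflux@example.org",
           role = c("aut", "cre"))
Description: A reproducible workflow for Seahorse XFe96 extracellular flux
    analysis of three-dimensional spheroid cultures: parsing of per-well
    OCR/ECAR rate tables with background correction and injection-phase
    labelling, spheroid morphometry (area, circularity, centroid) from
    fluorescence z-stacks, area-mediated viable-cell calibration and
    per-cell normalization, Mito Stress test parameter extraction with
    movement-artifact quality control, and multivariate metabolic
    phenotyping (coefficients of variation, min-max scaling, PCA,
    average-linkage clustering, bioenergetic maps). Includes a synthetic
    spheroid-cohort simulator so the full pipeline is testable without
    instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
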