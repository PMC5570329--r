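Package: nanosecrete
Title: Single-Cell Cytokine Secretion Analysis for Bead-Sensor Nanowell Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing dynamic single-cell cytokine secretion measured
    with antibody-coated bead biosensors in open nanowell arrays. Includes a
    finite-volume reaction-diffusion simulator of secreted-analyte transport and
    Langmuir surface capture on a bead, four-parameter logistic extraction of
    secretion kinetics (onset time, Hill slope, intensity ratio) from bead
    fluorescence time series, imaging-cytometry style phenotype gating with
    secretor-frequency, enrichment and multi-cell cooperation statistics, a
    seeded synthetic-data generator for nanowell experiments (occupancy,
    phenotypes, bead traces, rendered image frames), and an end-to-end pipeline
    from images to an analysis report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    minpack.lm,
    mclust,
    e1071,
    EBImage,
    tiff,
    tibble,
    dplyr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
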