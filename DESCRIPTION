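Package: pialflow
Title: Linescan Velocimetry, Vessel Diametry and Shear-Driven Remodeling
    of the Developing Pial Vasculature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies blood flow in surface (pial) vessels of the neonatal
    mouse cortex from two-photon linescan data. Red blood cell velocity is
    extracted from space-time linescan images (kymographs) by a
    Radon-transform streak-angle method with a cross-correlation fallback for
    fast flow, with windowed processing and quality-control rejection of
    movement artifacts. Vessel lumen diameter is measured as the full width
    at half maximum of a plasma-fluorescence intensity profile. Wall shear
    rate is estimated as 4*v/D under Poiseuille flow, and longitudinal
    observations are paired across consecutive imaging days to fit the
    regression of percent diameter change on log10 shear rate, with the
    study's >100% outlier-exclusion rule. A ground-truthed synthetic-data
    generator produces kymographs with commanded velocity, vessel profiles of
    known diameter, and longitudinal cohorts following a known remodeling
    law, so every stage of the pipeline is testable against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
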