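Package: gelswitch
Title: Switching Analysis of Thermoresponsive Collagen/Elastin Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for temperature-responsive collagen/elastin
    hydrogel actuators characterized by time-lapse imaging, confocal
    microscopy and circular dichroism. Tracks the projected gel area in
    top-view video by gradient-based circle fitting or threshold
    segmentation, extracts transition temperatures from the smoothed
    first derivative of area versus temperature, quantifies stroke,
    dose-response trends and per-cycle irreversible contraction under
    cyclic heating, decomposes fibril-network images into maximal
    inscribed circles to obtain pore-size distributions, and processes
    circular-dichroism spectra (reference subtraction, replicate
    averaging, high-tension voltage masking, normalization, band-feature
    extraction and two-component superposition fits). Ships synthetic
    generators for temperature protocols, contraction traces, rendered
    gel videos, fibril networks and CD spectra with known ground truth,
    so every stage is testable without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
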