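Package: hypoxamap
Title: Widefield Calcium and Hemodynamic Imaging Analysis Under Acute Hypoxia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-modality widefield imaging of the mouse
    cortex during acute hypoxia: demultiplexing of time-interlaced multicolor
    acquisitions, affine (optionally diffeomorphic) co-registration, modified
    Beer-Lambert spectroscopy of oxy-/deoxyhemoglobin and oxygen saturation,
    regression-based hemodynamic correction of calcium fluorescence, band-passed
    dF/F normalization, seed-based resting-state connectivity with Fisher-z
    epoch contrasts, and exact small-sample nonparametric statistics. Includes a
    forward simulator of the full acquisition (correlated calcium dynamics,
    hypoxia hemodynamic trajectories, Beer-Lambert optics, sensor noise and
    motion) so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    signal,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
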