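Package: beamqa
Title: Dosimetric Quality Assurance for Megavoltage Photon Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for quality assurance of radiotherapy photon-beam
    dosimetry. Provides gamma-index comparison of dose distributions
    (dose-difference / distance-to-agreement, e.g. 3%/3mm) with an
    independent brute-force verification oracle, percentage-depth-dose
    analysis (depth of dose maximum, PDD at depth, D20/D5), lateral beam
    profile metrics (flatness, symmetry, 80%-20% penumbra, geometric
    penumbra), and relative dosimetric factors (phantom output, head
    scatter, wedge). Includes an analytic photon-beam simulator that
    emulates Monte-Carlo-like depth-dose curves, profiles and 3-D dose
    grids for 6 and 12 MV beams, plain-text dose-grid and scan formats,
    and a DICOM RT Dose importer, so every analysis is reproducible
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
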