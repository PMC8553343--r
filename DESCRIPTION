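Package: marginscreen
Title: Dual-Channel Fluorescence Pre-Screening of Resected Tumor Margins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for fluorescence-based pre-screening of
    resected tumor margins with a dual-activatable molecular rotor probe.
    Provides photophysical calibration (Forster-Hoffmann viscosity law,
    linear nitroreductase titration, 3-sigma/k limit of detection),
    quantification of per-specimen maximal gray-scale intensity in a
    nitroreductase (green) and a viscosity (red) channel, derivation of a
    dual-channel decision threshold as the K-means centroid of a training
    scatter, three-group triage classification (definitely positive,
    suspiciously positive, negative), and evaluation of screening
    performance against H&E pathology labels. A synthetic-data module
    generates spectra, two-channel tissue images and margin cohorts with
    known ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
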