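Package: ggpgmr
Title: Gradient Guided-Mode Resonance Spectral Sensing: Forward Model and
    Assay Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward model of a compact spectral detection platform built
    from a gradient-grating-period guided-mode resonance (GGP-GMR) bandstop
    filter mounted on a linear CCD, together with the analysis pipeline that
    quantifies fluorescent and colorimetric liquid assays with it. The filter
    converts spectral information into spatial information: each grating
    period rejects its Bragg resonant wavelength, so the minimum-intensity
    corresponding pixel (MICP) of the CCD trace encodes the incident peak
    wavelength while its intensity encodes amplitude. The package models
    material dispersion and the slab-waveguide effective index, builds the
    device layout and its transmission-efficiency matrix, simulates CCD
    readout C = TI with instrument noise, performs monochromator-scan
    wavelength/pixel calibration, generates synthetic fluorescence
    (rhodamine-like dyes, albumin blue 580) and colorimetric (Jaffe
    creatinine, bromocresol-green albumin) assay datasets with retained
    ground truth, and computes dose-response regressions, sensitivity, noise
    and 3-sigma/slope limits of detection, plus cross-instrument agreement
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
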