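Package: hippo2p
Title: Analysis Pipeline for Transverse-Hippocampus Two-Photon Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative analysis stack for two-photon calcium
    imaging of the hippocampal transverse plane: point-spread-function
    characterization from fluorescent bead stacks and a geometric
    effective-NA resolution model; neuropil subtraction, dF/F baseline
    estimation and AR(2) sparse nonnegative deconvolution; floating
    circular-track behavior processing (circular medians, movement
    filtering, lap segmentation); place- and speed-cell classification with
    circular-permutation nulls and Skaggs spatial information; spatial
    information profiles along the DG-to-CA1 transverse axis with sliding
    windows, bootstrap and a general linear F-test; dendritic spine
    morphometrics, classification, turnover and survival; and glial-density
    versus implant-distance statistics. Every input can be generated
    synthetically with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    EBImage,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
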