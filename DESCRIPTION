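Package: gliospec
Title: Multimodal Optical Spectroscopy Classification of Brain Tumor Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free discrimination of normal brain and glioma
    tissue from fiber-probe optical spectra. Implements preprocessing of
    Raman, diffuse-reflectance and fluorescence spectra (instrument
    transmission correction, iterative sixth-order polynomial baseline
    removal, band and isosbestic-point normalization), ratiometric and
    scattering-slope classifiers, principal-component analysis with
    auROC-driven component selection, a random-search linear discriminant
    that maximizes the area under the ROC curve, stratified k-fold
    cross-validation, and multimodal score fusion. A class-conditional
    synthetic-spectra generator reproduces the statistical structure the
    analysis assumes (Raman band tables, hemoglobin-like pseudo-extinction
    curves with exact isosbestic points, EGFP fluorescence linear in tumor
    size) so the full pipeline is testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
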