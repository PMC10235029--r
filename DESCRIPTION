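Package: qusliver
Title: Quantitative Ultrasound Imaging of Liver Steatosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative ultrasound (QUS) tissue characterization of fatty
    liver.  Implements simultaneous estimation of relative backscatter and
    attenuation coefficient maps from block-wise log spectral ratios via a
    total-variation regularized power-law inversion, envelope-SNR guided
    region-of-interest selection, fat-vacuole segmentation of H&E histology
    with Brunt steatosis grading, and a Gaussian-process regression that
    predicts fat fraction from QUS features under leave-one-out
    cross-validation.  A synthetic-data module generates radiofrequency
    speckle volumes, block spectra, histology images and whole cohorts with
    known ground truth so that every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    Matrix,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
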