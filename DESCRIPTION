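Package: basalact
Title: Quantification of Basal Actomyosin Networks in Epithelial Tissue
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for basal actomyosin organisation in epithelial
    monolayers such as the Drosophila follicular epithelium. Quantifies stress
    fibers from fluorescence line profiles by SD-thresholded peak detection,
    junctional (cortical) F-actin with a 2-um bar centred on cell-cell
    boundaries, actomyosin oscillation period and amplitude via adjacent-peak
    intervals and the power spectrum of the autocorrelation, recoil velocity
    after laser ablation of cell bonds as a membrane-tension proxy, and
    per-cell morphometry on label images. Ships a synthetic-data generator
    (mosaic confocal-like scenes, coupled oscillation traces, vertex-distance
    recoil traces, morphometric tables) with recorded ground truth so every
    stage is testable without imaging data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
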