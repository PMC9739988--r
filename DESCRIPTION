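Package: TILquant
Title: Machine-Learning Quantification of Tumor-Infiltrating Lymphocytes in
    H&E Histology with Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for quantifying tumor-infiltrating
    lymphocytes (TILs) from hematoxylin-and-eosin histology images and
    relating the resulting scores to patient survival. Provides H&E stain
    estimation and color deconvolution in optical-density space, watershed
    nucleus detection with physical-unit parameters, per-cell morphometric
    and intensity features with Gaussian neighborhood smoothing, a seeded
    multilayer-perceptron cell classifier over tumor/immune/stroma/ignore
    classes, the four electronic TILs variables (eTILs%, esTILs%, etTILs%,
    eaTILs), maximally selected log-rank cut-point discovery with
    multiplicity-corrected inference, Kaplan-Meier and Cox
    proportional-hazards modelling, and synthetic histology tile and
    survival cohort generators with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    survival,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBasedAssays, Classification, Survival, Software
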