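Package: pelviseg
Title: Pelvic Bone Segmentation and Evaluation for Multiparametric MRI
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for multi-label segmentation of pelvic bony structures
    on diffusion-weighted (DWI) and apparent diffusion coefficient (ADC)
    volumes, and for its quantitative and qualitative evaluation. Provides a
    seeded generator of synthetic pelvic label phantoms with paired DWI/ADC
    intensity volumes and controlled segmentation perturbations; NIfTI input
    and output with geometric and intensity preprocessing; a configurable,
    CPU-trainable 3D U-Net segmentation network; connected-domain extraction,
    matching, and overlap-condition classification; Dice similarity
    coefficients, physical bone volumes, Bland-Altman agreement, linear fits
    and single-measure intraclass correlation; and a modality-aware
    connected-domain scoring rubric aggregated from component to label to
    patient level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
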