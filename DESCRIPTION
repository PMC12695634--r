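Package: gvmux
Title: Pressure-Domain Multiplexed Ultrasound Imaging of Acoustic Reporter Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for two-tone ultrasound imaging of gene
    expression with acoustic reporter genes (ARGs). Provides a parametric
    forward model of gas-vesicle nonlinear pressure responses with
    irreversible collapse, seeded synthetic-data generators for reference
    curves, 2-D image series, 96-well screening plates and protein variant
    libraries, pixelwise non-negative least-squares spectral unmixing into
    per-reporter acoustic channels (including a depth/attenuation-corrected
    variant), quantitative directed-evolution screen analytics (automated
    ROI placement, QC filters, threshold/yield/collapse estimators,
    acoustic-map fitting, contrast-to-noise metrics), and pairwise global
    protein alignment distance scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml,
    tiff,
    mgcv,
    withr,
    Biostrings,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
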