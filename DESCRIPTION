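Package: conecounter
Title: Automated Cone Photoreceptor Counting on Flat-Mounted Retinas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for automated quantification of
    cone photoreceptors on flat-mounted retinas imaged by fluorescence
    microscopy. Provides a synthetic-retina generator with per-cone ground
    truth, an acquisition model (grid construction, two-stage autofocus,
    nine-plane Z-stacks written as multi-page TIFF), a spot-detection chain
    (best-focus projection, Otsu auto-threshold, field quality control,
    tile-local thresholding, top-hat filtering and watershed dissociation of
    touching cells), global and unbiased counting-frame stereological density
    estimators, a virtual eye-fundus spatial density map, and the statistical
    layer (Welch and paired t-tests, two-way ANOVA, quantile-quantile
    equalization of counting methods).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    car,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
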