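Package: canopybiomass
Title: UAV Canopy Traits and Wheat Biomass Prediction at Plot Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating aboveground wheat biomass from
    UAV-derived plot imagery. Generates synthetic plot scenes (multiband
    reflectance plus canopy height) with known ground truth, extracts 66
    spectral and 9 geometric traits per region of interest using OSAVI-Otsu
    canopy masking, classifies broad growth stages from a thermal-time
    phenology spline, selects features by recursive feature elimination with
    a partial-least-squares base learner, trains and compares four learner
    families under repeated k-fold cross-validation, and estimates
    within-season repeatability of predicted biomass with a row-column
    spatial mixed model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    ranger,
    kernlab,
    xgboost,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
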