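Package: tractwmh
Title: Tract-Level White Matter Hyperintensity Burden and Regional Amyloid-PET SUVr
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline linking white matter hyperintensity
    (WMH) burden inside default mode network (DMN) fiber tracts to amyloid-PET
    standardized uptake value ratios (SUVr) in the connected cortical regions.
    Provides histogram-Gaussian WMH segmentation of FLAIR-like images at a
    mean + k*SD threshold with connected-component cleanup, tract-masked lesion
    volumetrics with log transformation, composite-ROI SUVr quantification
    normalized by a whole-cerebellum reference, and an adjusted linear regression
    family (standardized beta, adjusted R-squared, Cohen's f) with Bonferroni
    control. A synthetic phantom-cohort generator with known ground truth makes
    every stage verifiable without access to subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
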