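Package: coldpheno
Title: Cold-Stress Phenotyping and Risk Prediction from Leaf Spatial
    Variability Features
Version: 0.1.0
Authors@R:
    person("coldpheno", "developers", email = "coldpheno@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-data-driven pipeline for
    monitoring low-temperature stress in strawberry (Fragaria x ananassa)
    from imaging phenotypes. Generates seeded synthetic experiments
    (chlorophyll-fluorescence frame stacks, band reflectance images, hourly
    temperature profiles, leaf physiology), computes thirteen phenotypic
    parameter maps (eight PAM quenching parameters, five normalized
    difference spectral indices), extracts sixteen spatial-variability
    features on vein-parallel and vein-perpendicular transects and an
    inscribed leaf region (624 features per plant), ranks features by
    mutual information, builds the Photosynthetic Physiological Potential
    Index (PPPI), the relative negative accumulated temperature (RNAT) and
    the Cold Damage Risk Index (CDRI = PPPI - RNAT/650), inverts PPPI and
    RNAT with in-package tree ensembles (gradient boosting, AdaBoost.R2,
    random forest) tuned by 5-fold cross-validation, classifies five cold
    damage risk levels, and explains the fitted models with exact Shapley
    attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
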