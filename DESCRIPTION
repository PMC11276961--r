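Package: rangedyn
Title: Ensemble Species Distribution Models and Range-Shift Indices on
    Synthetic Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for invasion-ecology range
    dynamics: occurrence cleaning and 5-km spatial thinning, derivation of
    the 19 bioclimatic variables from monthly climate, terrain predictors
    from a digital elevation model, Pearson/jackknife predictor selection,
    gated multi-algorithm ensemble species distribution models with
    pseudo-absence sampling and repeated cross-validation, maximum
    sensitivity-specificity binarization into potential ranges, and
    per-species and multi-species range-shift indices (range expansion
    ratio, range similarity index, expanding ranges, overlap indices of
    habitat suitability and potential range, invasion hotspots). A virtual
    study system generator (correlated climate, land-use and terrain
    rasters plus niche-driven occurrences with known truth) makes every
    stage verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
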