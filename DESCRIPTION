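Package: pepperview
Title: Viewpoint Analysis for Sweet Pepper Maturity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how camera viewpoint and fruit orientation affect
    colour-based maturity classification of sweet peppers. Includes a synthetic
    multi-viewpoint RGB(-D) fruit image generator with analytically known
    ground truth, two pepper-from-background segmentation algorithms
    (threshold plus Chan-Vese active contours for dark-background photocell
    images; a depth/colour/edge pipeline for cluttered RGB-D scenes), pooled
    colour-statistic feature extraction, random-forest maturity
    classification, and viewpoint scenario analysis (classification accuracy,
    optimistic and pessimistic bounds over viewpoint combinations, and
    Cohen/Light kappa inter-viewpoint agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    randomForest,
    rlang,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
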