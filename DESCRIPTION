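Package: rootarch
Title: Root System Architecture Classification from Root Crown Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for objective classification of excavated root crowns into
    branch-rooted, tap-rooted and intermediate architecture types. Generates
    labelled synthetic binary root-crown images, extracts a 38-trait
    morphological feature vector per crown (skeleton, distance-transform
    diameters, holes, angles, convex hull), performs constrained
    rotation/scale image augmentation, benchmarks six classifiers (k-means,
    PAM, random forest, naive Bayes and two multilayer perceptrons) under
    repeated stratified cross-validation with seven per-class quality
    metrics, and grades predictions into probability confidence tiers for
    breeding selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    randomForest,
    e1071,
    cluster,
    png,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
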