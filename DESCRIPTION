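Package: litchistereo
Title: Recognition, Stereo Matching and Localization of Clustered Litchi Fruits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Binocular-vision pipeline for detecting clustered mature litchi
    fruits in orchard imagery and localizing them in three dimensions. Fruit
    regions are segmented by four supervised patch classifiers (Gaussian naive
    Bayes, cosine-similarity k-nearest-neighbours, a three-layer sigmoid
    back-propagation network and a linear support vector machine) working on a
    ten-dimensional colour/texture feature vector (R-B, HSI intensity, Cb, b*
    and the six Tamura texture features). Per-classifier binary masks are
    cleaned morphologically, single fruits are extracted by a circle Hough
    transform over radii 30-50 px, the four detection sets are fused by an OR
    rule, and fruits are grouped into single/pair/multiple cluster categories
    by a 40-pixel geometric-centre rule. Cluster labels are matched across a
    rectified stereo pair by normalized cross-correlation along the epipolar
    row with ordering constraints, and matched clusters are triangulated with
    a pinhole camera model. A seeded synthetic stereo-scene generator with
    full ground truth and the evaluation metrics used for orchard trials make
    the whole pipeline testable without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
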