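Package: otogene
Title: Audiogram-Based Gene Prioritization for Autosomal Dominant
    Nonsyndromic Hearing Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate autosomal dominant nonsyndromic hearing loss
    (ADNSHL) genes from pure-tone audiograms. Implements a single-instance
    stacked ensemble (k-nearest-neighbour, adaptive boosting and random
    forest submodels trained on data partitions by gene data volume,
    patient age and audiogram shape, fused by regularized multinomial
    logistic regression) and a multi-instance classifier for patients with
    repeated audiograms (pairwise margin classifiers with sigmoid
    probability calibration combined by iterative pairwise coupling, then
    bag-level aggregation). Provides per-gene audioprofiles (mean
    thresholds by age group), fitted audioprofile surfaces (threshold as a
    polynomial function of age and frequency), k-means clustering and 3D
    embedding of the audiometric feature space, top-3 gene ranking with a
    green/red confidence flag, evaluation metrics, a seeded synthetic
    audiogram simulator, and JSON exports for dashboard-style
    visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    randomForest,
    rpart,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
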