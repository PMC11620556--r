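Package: kcbgwo
Title: K-Means-Clustered Grey Wolf Optimization and Extreme Learning
    Machines for Diabetic Retinopathy Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diabetic retinopathy (DR) grade classification and
    retinal lesion screening built around a k-means-clustered grey wolf
    optimizer (KCBGWO). Provides the optimizer in continuous and binary
    (sigmoid-transfer) modes, a ten-function benchmark suite with a
    multi-run trial protocol, an extreme learning machine (ELM) trained in
    closed form via the Moore-Penrose pseudoinverse, the coupled
    KCBGWO-ELM classifier with feature-fusion bookkeeping and class
    balancing, one-vs-rest classification metrics with ROC/AUC and the
    Jaccard overlap coefficient, and a rule-based screening procedure for
    dark (red-lesion-like) and bright (exudate-like) regions in fundus-like
    images, together with synthetic generators for feature sets and rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    yaml,
    png,
    optparse
Config/testthat/edition: 3
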