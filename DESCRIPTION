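Package: ramil
Title: Ranking-Attention Multiple Instance Learning for Weakly Supervised
    Volume Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bag-level binary classification of 3D image volumes treated as
    bags of 2D slices, using attention-scored instance features, top-C ranked
    selection with unrescaled weights, and a sigmoid classification head
    trained with a class-weighted cross-entropy loss. Includes baseline
    mean/max/attention/gated-attention pooling, stratified cross-validation
    with early stopping on validation AUC, rank-based AUC with bootstrap
    confidence intervals, Mann-Whitney U comparisons between models,
    attention-based slice ranking with Grad-CAM heatmaps, DICOM-series and
    PNG-directory preprocessing, and a synthetic witness-bag generator that
    makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    png,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
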