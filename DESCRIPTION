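Package: smklfs
Title: Embedded Feature Selection for Expression Data via Multiple Kernel Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage feature selection for labeled expression matrices
    (tumour versus adjacent-normal and similar two-class designs) built on
    multiple kernel learning. Stage one ranks every feature by the optimal
    value of a SimpleMKL support-vector-machine objective computed on that
    feature alone; stage two greedily grows a compact feature subset by the
    reduction of the same objective. Includes the surrounding preprocessing
    chain (missingness filtering, local least squares imputation,
    probe-to-gene merging by maximum, per-sample median-absolute-deviation
    normalization), feature-space performance measurements (mean and max
    effectiveness under cross-validation, union and independent stability
    under resampling, similarity between methods), a seeded generator of
    synthetic expression data with planted informative, redundant and
    irrelevant features, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
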