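Package: nasrec
Title: Natural Action Structures for Video Action Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compiles natural action structures (NAS) - multi-size,
    multi-scale spatial-temporal concatenations of local features - from
    grayscale video and uses them as code words for action recognition.
    Provides the cuboid spatiotemporal interest-point detector, coupled
    multi-scale circular patch sampling, independent component analysis of
    patch sequences with Gabor-function fitting and clustering, two-level
    K-means codebook construction with discriminative structure selection,
    and two classification back ends: a one-vs-rest support vector machine
    with the 1-chi-squared histogram kernel on grid-pooled NAS histograms,
    and per-action latent Dirichlet allocation fitted by variational EM.
    Includes a deterministic synthetic action-video generator and the
    leave-one-subject-out evaluation protocol with scale and noise
    robustness variants.
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
    ggplot2,
    minpack.lm,
    kernlab,
    png,
    jsonlite,
    EBImage,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
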