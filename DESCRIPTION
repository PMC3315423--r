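Package: morphrel
Title: Scanner Reliability Analysis for Multicentre Brain Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the reliability of brain morphometry in
    multicentre, test-retest MRI studies. Implements variance-component
    estimation for balanced crossed random-effects designs via expected
    mean squares, between-centre and between-visit reliability statistics
    with categorical grading, ANCOVA-style F-tests for centre and visit
    effects with brain-volume and gyrification covariates, bias-correction
    quality metrics on grey-level volumes (within-mask coefficient of
    variation, white/grey matter contrast from histogram peaks), and
    synthetic generators for morphometry tables with known variance
    structure and 3-D tissue phantoms with multiplicative bias fields.
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
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
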