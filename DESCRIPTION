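Package: burntex
Title: Burn Severity Classification from B-Mode Ultrasound Texture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture-based classification of thermal burn severity from
    greyscale B-mode ultrasound images. Builds grey-level co-occurrence
    matrices (GLCM) for an arbitrary pixel offset, derives the classical
    second-order (Haralick-family) texture features, performs sequential
    backward feature selection under leave-one-out cross-validation,
    and classifies burn groups pairwise with a radial-basis-function
    support vector machine and multiclass with kernel Fisher discriminant
    analysis. Includes a synthetic speckle-phantom generator that emulates
    the growth of low-intensity speckle regions with burn severity, so the
    whole pipeline is testable without clinical data, plus the
    sensitivity/specificity-based minimum-sample-size formula for
    diagnostic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
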