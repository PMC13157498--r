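Package: patchalign
Title: Patch-Level Image-Text Alignment for Weakly Supervised Lesion
    Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contrastive vision-language training with patch-level alignment
    losses for weakly supervised abnormality localization in grayscale
    medical-style images. Provides a seeded synthetic phantom generator with
    planted elliptical lesions and box annotations, patch-grid geometry and
    bounding-box to patch-mask supervision, a scale-configurable vision
    transformer with text encoder and attention-pooling combiner trained by a
    built-in reverse-mode autodiff tape, the global, linear-combination,
    patch and combined-patch loss terms, zero-shot patchwise inference, and
    distance-based Hungarian-matched FROC evaluation with sensitivity at
    fixed average false-positive rates.
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
    png,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
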