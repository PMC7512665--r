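Package: ordinalhrv
Title: Ordinal-Pattern Entropy Analysis of Heart-Rate-Variability Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies the complexity of RR-interval (heart-rate-variability)
    time series with ordinal-pattern methods: permutation entropy and
    permutation min-entropy estimated over a grid of embedding dimensions and
    delays. Includes ECG preprocessing (symlet-8 wavelet denoising,
    difference-threshold R-peak detection, interval extraction and automated
    artifact rejection), a synthetic cohort generator for paired multi-state
    designs with controllable temporal-correlation strength, a paired
    statistical layer comparing emotional states against a neutral baseline
    (normality checks, paired t-tests, relative-increment sensitivity), and a
    reproducible end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
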