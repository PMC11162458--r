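Package: delaynorm
Title: Delayed Normalization Models for Widefield Imaging Temporal Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying temporal additivity of stimulus-evoked
    widefield imaging responses (VSDI, GCaMP) in visual cortex. Fits
    two-component models to trial time courses: a fast stimulus-evoked
    component (a linear filter, or a delayed divisive-normalization stage,
    driven by the stimulus time course) plus a slow stimulus-independent
    trend expanded in raised-cosine bases. Includes per-condition filter
    diagnostics, leave-one-condition-out cross-validation, a power-law
    sub-additivity exponent, contrast-homogeneity simulation, and a
    synthetic trial generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
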