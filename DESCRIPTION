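Package: vfasym
Title: Visual Field Asymmetries in BOLD Responses to Natural Image Patches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying whether responses in low-level visual cortex
    depend on the match between where a natural image patch is presented
    (upper or lower visual field) and where it was sourced relative to the
    centre of gaze (above or below fixation). Implements rapid event-related
    design generation with BIDS-style event tables, quadrant patch extraction
    with raised-cosine windowing, a BOLD forward simulator (HRF-convolved
    condition regressors, polynomial drift, ARMA(1,1) noise), GLM estimation
    with ARMA(1,1) prewhitening and percent-signal-change conversion,
    repeated-measures ANOVA with Huynh-Feldt correction, preference ranking,
    and image characterisation in DKL colour space via an odd-symmetric Gabor
    filter bank.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
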