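Package: concord
Title: Design and Analysis of Multi-Reader Concordance Trials for
    AI-Based Diagnostic Imaging Devices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical design and analysis machinery for clinical trials
    that evaluate an AI-based diagnostic imaging device by its concordance
    with human radiologists when no gold standard exists.  Implements a
    one-sided non-inferiority test of the device-radiologist concordance
    rate against the radiologist-radiologist concordance rate with a
    similarity margin, a two-sided test comparing device concordance with
    senior versus junior radiologists, the compound correlation algebra
    linking per-indicator correlations to per-subject concordance score
    correlations, closed-form power and sample-size formulas for both
    objectives, a correlated binary data simulator based on dichotomized
    latent multivariate normal vectors with exactly matched pairwise
    binary correlations, and a Monte-Carlo study driver that reports
    empirical type-I error and power over design grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
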