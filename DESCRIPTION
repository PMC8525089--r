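Package: lakeddg
Title: Depth Diversity Gradients of Submerged Macrophytes in Deep Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the depth diversity gradient (DDG) of
    submerged macrophytes from transect survey data: additive alpha/beta/gamma
    richness partitioning per depth class, peak measures (D_max, R_max) with
    tie-averaging and pattern-type classification, heteroscedasticity-robust
    simultaneous max-t depth contrasts, PCA-based reduction of physiochemical
    drivers with axis naming, additive mixed models with backward selection and
    drop-contribution scoring, invariability coefficients and per-lake linear
    trend tables, plus a seeded synthetic lake-system generator with known
    niche structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich,
    mgcv,
    vegan
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
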