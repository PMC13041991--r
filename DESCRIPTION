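Package: stackenc
Title: Stacked Ridge Encoding Models for Naturalistic fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Grayordinate-wise stacked ridge encoding models for naturalistic
    movie-viewing fMRI. Fits per-feature-space ridge regressions with nested
    cross-validation, combines them with simplex-constrained stacking weights
    solved as a convex quadratic program, and derives explained variance,
    unique (partitioned) variance, and weight-difference preference indices.
    Includes temporal-permutation significance testing with false discovery
    rate correction, parcel-level pooling, Spearman-Brown corrected split-half
    noise ceilings, framewise-displacement quality control with a threshold
    sweep, sensory phenotype scoring, parcel-wise mixed-effects group and
    severity models, and a synthetic-data generator with known ground-truth
    mixing weights for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
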