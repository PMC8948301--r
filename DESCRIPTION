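Package: fractalCTP
Title: Four-Dimensional Blanket Fractal Analysis of Dynamic Myocardial
    CT Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Local fractal analysis of four-dimensional (3D + time) dynamic
    contrast-enhanced cardiac CT perfusion imaging. Implements the blanket
    (Minkowski cover) estimator of local fractal dimension extended to 4D
    hypertextures, maximum-upslope estimation of a myocardial blood flow
    surrogate, denoising and Hounsfield-to-concentration standardization,
    AHA 17-segment aggregation, and threshold classification of normal,
    microvascular and macrovascular perfusion states with a full
    diagnostic-statistics layer (exact binomial confidence intervals,
    weighted Cohen's kappa, McNemar, Bland-Altman, Hand-Till multi-class
    AUC, rank-based group tests). Ships a synthetic 4D perfusion-phantom
    generator with fractional-Brownian perfusion texture and known
    ground-truth lesions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-array.R'
    'phantom.R'
    'preprocess.R'
    'fractal.R'
    'perfusion.R'
    'segments.R'
    'stats-classify.R'
    'stats-diagnostics.R'
    'io.R'
    'pipeline.R'
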