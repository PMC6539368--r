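Package: harensemble
Title: Diversity-Enhanced Classifier Ensembles for Accelerometer-Based
    Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-layer diversity-enhanced multiclassifier pipeline for
    human activity recognition from a single waist-worn tri-axial
    accelerometer. Sliding-window time-domain, autoregressive and
    frequency-domain features are projected with kernel Fisher
    discriminant analysis (RBF kernel, ridge-regularized dual
    eigenproblem); extreme learning machine base classifiers are trained
    on bootstrap resamples with per-member hidden-neuron selection; base
    classifiers are then ranked by a combined diversity criterion
    (disagreement, Cunningham entropy, coincident failure diversity) and
    the top-ranked subset is fused by majority vote. Includes a seeded
    synthetic accelerometer-signal generator, leave-one-subject-out
    evaluation, strategy comparison utilities, and command-line entry
    points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'features.R'
    'kfda.R'
    'elm.R'
    'diversity.R'
    'evaluation.R'
    'simulate.R'
    'io.R'
    'config.R'
    'experiment.R'
    'harensemble-package.R'
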