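Package: ahvtools
Title: Tuning, Tracking and Decoding of Angular Head Velocity Signals in
    Cortical Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for angular head velocity (AHV)
    coding in cortical single-unit recordings. Provides kinematic extraction
    from 2-D head tracking, classification of head-direction-, AHV- and
    speed-tuned units against spike-time-shift permutation nulls, chronic
    single-unit tracking across recording sessions via waveform and
    inter-spike-interval similarity with dynamic time warping, passive
    rotation response statistics, single-cell ROC discrimination with DeLong
    confidence intervals, population decoding with shrinkage linear
    discriminant analysis, cross-correlogram detection of putative
    monosynaptic connections, go/no-go psychophysics scoring, and seeded
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    pROC,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'core_io.R'
    'synthetic.R'
    'kinematics.R'
    'tuning.R'
    'matching.R'
    'rotation.R'
    'roc.R'
    'decoding.R'
    'connectivity.R'
    'behavior.R'
    'pipeline.R'
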