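Package: equigait
Title: Simulation, Stride Feature Extraction and Classification of Equine Gaits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying quadruped gait classification from inertial
    measurement unit (IMU) data. Provides a synthetic generator of per-limb
    footfall timelines and multichannel sensor streams for eight equine gaits
    (walk, trot, left/right canter, toelt, pace, paso fino, trocha),
    stride segmentation and extraction of the classical stride-timing and
    interlimb-coordination variables (duty factor, advanced placements,
    support-phase statistics, limb-pair overlaps), projection into the
    Hildebrand gait diagram, a suite of supervised classifiers over stride
    features and over windowed raw signals (including a long short-term
    memory sequence model), and horse-disjoint grouped cross-validation
    with confusion-matrix reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    rpart,
    ranger,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
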