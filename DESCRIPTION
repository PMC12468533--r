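Package: gaitsense
Title: Wearable Gait and Breathing Monitoring Pipeline for TUG and Balance Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and machine-learning pipeline for an
    optoelectronic wearable system combining a lumbar inertial measurement
    unit (IMU) with a fiber-optic chest belt. Provides spectral breathing-rate
    estimation from optical-intensity traces with clinical regime
    classification and silhouette-selected K-means clustering of breathing
    rates; Random-Forest segmentation of the seven Timed-Up-and-Go (TUG)
    phases with first/last-detection interval extraction and conventional
    fall-risk scoring; multi-output Random-Forest regression of postural
    balance indices (anterior and medial displacement, local fractal
    stability); and a synthetic-signal generator that produces labeled IMU,
    optical and quiet-stance traces with known ground truth so that every
    stage is testable without access to recorded subject data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    cluster,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
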