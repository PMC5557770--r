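Package: prefog
Title: Characterization and Prediction of the Pre-Freezing-of-Gait Phase
    from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying the short phase of gait
    degradation that precedes freezing-of-gait (FOG) episodes in
    Parkinson's disease, using tri-axial accelerometer and gyroscope
    streams from ankle- and lower-back-mounted inertial sensors.
    Provides window segmentation with a sufficient-motion check, eight
    gait features (turning degrees, left-right cross-correlation and SD
    statistics, trunk SD, locomotor- and freezing-band power, freezing
    index), paired per-condition statistical comparison with
    Benjamini-Yekutieli correction, a probabilistic linear-discriminant
    pre-FOG classifier evaluated leave-one-subject-out, and a synthetic
    multi-sensor recording generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
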