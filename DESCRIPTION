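Package: actifuse
Title: Multimodal Activity Recognition from Wrist Inertial Data and
    Egocentric Object Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes activities of daily living by fusing sliding-window
    time- and frequency-domain features from two wrist-worn accelerometers
    with hand-object interaction features derived from per-frame object
    detections of an egocentric camera. Implements timespan-defined
    windowing, stillness-based temporal alignment of devices, early fusion
    (feature concatenation) and late fusion (probability stacking),
    leakage-aware de-overlapping of windows, repeated cross-validation,
    cross-subject fixed-split and grid-search evaluation protocols, and a
    fully controllable synthetic scenario generator for end-to-end testing
    without wearable recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    randomForest,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
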