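Package: aegdi
Title: Gait Recognition from Wearable Inertial Sensors via Angle Embedded
    Gait Dynamic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end gait recognition from triaxial accelerometer and
    gyroscope recordings collected by casually worn devices. Detects gait-cycle
    starting positions in the acceleration magnitude signal with a grid-based
    greedy segmentation algorithm, encodes each cycle as an Angle Embedded Gait
    Dynamic Image (AE-GDI) -- a time-delay angle embedding that is invariant to
    rotation, translation and uniform scaling of the sensor frame -- and
    classifies AE-GDIs with a compact convolutional neural network for both
    binary authentication and multi-subject labeling. Includes a seeded
    synthetic multi-subject gait simulator with known ground truth, the GDI
    inner-product and overlap-window baselines, a temporal-convolution (TCNN)
    ablation, and evaluation protocols with precision/recall/accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
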