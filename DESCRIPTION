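Package: equiback
Title: Quantifying Equine Back Flexion/Extension from Trunk-Mounted IMUs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an accelerometer-only method for quantifying the
    global flexion/extension angle of a horse's back from three trunk-mounted
    inertial measurement units (withers, eighteenth thoracic vertebra, and
    pelvis), together with the optical motion-capture reference computation
    and the agreement-statistics suite (Bland-Altman limits of agreement,
    ordinary least products regression, Pearson correlation) used to validate
    such methods. Includes gravity-based sensor orientation correction,
    drift-controlled double integration of vertical acceleration, gait-cycle
    segmentation of the angle trace into per-cycle flexion and extension
    ranges, and a synthetic trunk-motion simulator with analytic ground truth
    for end-to-end testing without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    pracma,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
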