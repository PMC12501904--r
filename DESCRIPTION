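Package: cswear
Title: Circadian Stimulus Computation and Calibration for Wearable Light
    Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes circadian light (CL_A) and circadian stimulus (CS)
    from spectral power distributions using the Rea phototransduction
    model, estimates photopic illuminance and correlated color temperature
    by Planckian-locus search, and calibrates wearable light-logger
    outputs (raw lux, raw CCT, R/G/B/IR channel irradiances) against
    spectrophotometer ground truth with no-intercept linear models.
    Includes a scene and sensor simulator emulating laboratory and
    nursing-home lighting protocols, linear and random-forest CS
    prediction with cross-validation and permutation importance, and
    deployment analytics: day/night exposure summaries, weekly paired
    comparisons, post hoc power, nonwear detection, and dim-light CCT
    masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
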