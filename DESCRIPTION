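Package: freegaze
Title: Free-Viewing Gaze Analysis for Fixational and Nystagmic Eye Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-based analysis of free-viewing eye-tracking recordings in
    cohorts that include nystagmus, where fixation detection is impossible:
    polynomial five-point calibration, instantaneous gaze velocity via a
    smoothed central-difference operator, coverage-corrected spatial entropy
    of gazed grid cells, construction of empirical (leave-one-out),
    luminance-contrast and externally supplied predictor maps, bias-controlled
    AUC classification of gazed versus nongazed locations (with shuffled-map,
    time-binned and velocity-binned variants), repetition (short-term memory)
    contrasts, and the group-level statistical models. Ships a synthetic
    cohort generator emulating fixation-saccade and jerk or multiplanar
    nystagmus kinematics so the full pipeline is testable without data
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    lmerTest,
    tibble,
    dplyr,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
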