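Package: wristcomp
Title: Myoelectric Wrist Control, Trunk Compensation and Cognitive Load Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for validation studies of multi-articulate
    myoelectric prostheses. Provides a calibrated synthetic-study generator
    (surface EMG driven by three-degree-of-freedom kinematic intent, IMU
    orientation streams with trunk lean/bend excursions, detection-response-task
    logs, clothespin-task outcomes and NASA-TLX scores), an EMG feature chain
    (causal Butterworth band-pass, power-line notches, all differential channel
    pairs, 300-ms smoothed mean-absolute-value features at 30 Hz), a
    linear-Gaussian Kalman decoder with per-DOF software locking, quaternion
    orientation fusion and trunk lean/bend angle extraction with per-attempt
    maximum absolute deviation, detection-response-task scoring with the 2.5-s
    ISO reclassification rule, and the study's statistical battery: log-link
    binomial GLMs with marginally standardized proportions, linear models with
    HC1 sandwich variance, and within-participant Monte Carlo permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    sandwich,
    lmtest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
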