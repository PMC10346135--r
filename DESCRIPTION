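Package: kinagree
Title: Agreement Validation of Wearable IMU Joint Kinematics Against
    Optoelectronic Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to validate range-of-motion (ROM) measurements from a
    single body-worn inertial measurement unit (IMU) against an
    optoelectronic motion-capture reference. Provides a synthetic paired
    kinematics generator with known ground truth (rest/ramp/hold repetition
    cycles, sensor noise, inter-system offset, integer-sample lag, stomp
    synchronization artifacts, and sensor misplacement modeled as an axial
    frame rotation), quaternion/Euler orientation conversions under ZYX and
    YXZ sequences, stomp-artifact cross-correlation time synchronization,
    local-minima repetition segmentation with a working-phase ROM statistic,
    a method-agreement suite (accuracy, RMSE, Pearson and Lin concordance
    correlations, Bland-Altman limits of agreement, SEM/MCID,
    Anderson-Darling normality), and a sensor-misplacement sensitivity
    analysis, plus an end-to-end simulated validation-study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
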