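Package: wheelmetrics
Title: Multi-Sensor Wheelchair Mobility Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing and statistical analysis for instrumented manual
    wheelchairs carrying wheel-hub gyroscopes, a piezoresistive pressure
    seat mat and a GPS receiver. Provides two-point clock synchronisation
    (offset and skew) from trigger-spike pentads, cambered differential-drive
    odometry (frame speed, yaw rate, turning radius, calibrated distance),
    micro-degree GPS conversion to local metres, seat-mat calibration and
    force-weighted centre-of-pressure estimation, alignment of signals onto a
    common distance grid, per-section statistics with Tukey HSD and Cohen's d
    effect-size networks, and a rank-based route-compliance analysis
    (pairwise R-squared, rank sums, Kendall's W). A synthetic-run generator
    with known ground truth emulates a 13-section urban course so every
    stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
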