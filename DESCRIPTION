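Package: gaitload
Title: Biomechanical Loading Analysis of Distance Running from Wearable
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Gaitload", "Developers", email = "gaitload@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying external biomechanical loading in
    distance running from tri-axial accelerometer streams recorded at the
    distal tibiae and the sacrum. Provides a calibrated synthetic signal
    generator (alternating-leg impact transients at 120 Hz), gait event
    segmentation by vector-magnitude peak detection, per-bout metrics
    (cadence, peak tibial acceleration, lateral asymmetry, residual
    shock), ventilatory-threshold based speed-zone prescription with an
    altitude intensity adjustment, and three-way repeated-measures ANOVA
    with Greenhouse-Geisser correction, Bonferroni post hoc comparisons
    and Cohen effect-size ratings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
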