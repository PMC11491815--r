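Package: accelflight
Title: Flight Activity and Effort of Songbirds from Tri-Axial Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse flight activity and flight effort of small
    songbirds from body-mounted tri-axial accelerometers. Provides a
    synthetic-data generator that emulates a miniature logger (quantized
    +/-8 g, 8-bit output) recording six behaviour classes including bounding
    flight; signal transforms (quantization, subsampling, running-mean static
    acceleration, dynamic body acceleration and VeDBA); window-based behaviour
    classification with gradient-boosted trees; flight-bout segmentation with
    single-window gap filling; per-bird activity and effort metrics; Weibull
    distributional regression of per-flight effort on log flight duration;
    wing morphometrics (wing loading, aspect ratio, weight-normalized wing
    area); group comparisons (Welch and paired t-tests, one-way ANOVA,
    Pearson correlation, loess time-of-day trend); and back-of-the-envelope
    ecological extrapolations of daily flight time, distance and foraging
    radius.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
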