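Package: mdpa
Title: Multidimensional Physical Activity Profiles and Wearable-Feedback Trial
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for turning minute-by-minute wearable energy-expenditure
    records into multidimensional physical activity profiles (physical activity
    level, sedentary time, daily moderate-intensity minutes, bouted MVPA and
    vigorous activity, steps), for evaluating traffic-light health targets with
    activity review and forward planning, and for analysing two-arm trials of
    such profiles with baseline-adjusted ANCOVA, bias-corrected and accelerated
    (BCa) bootstrap confidence intervals and Hedges g effect sizes. Includes a
    calibrated minute-level synthetic cohort generator so the full pipeline can
    be exercised and validated end to end without access to raw device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
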