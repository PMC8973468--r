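Package: pupilload
Title: Cognitive-Load Analysis of Task-Evoked Pupillary Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for estimating the difficulty of working-memory tasks
    from pupil-diameter recordings. Preprocesses raw binocular traces from a
    digit-span experiment (blink/invalid-record removal, binocular averaging,
    a 20 percent invalid-trial rule, Savitzky-Golay smoothing), extracts seven
    per-trial pupillometric features (baseline pupil size, mean pupil diameter
    change, average percentage change, peak dilation, pupil-size entropy, time
    to peak, peak dilation speed), tests per-feature difficulty effects with
    subject-level linear mixed models and likelihood-ratio tests, and
    classifies trial difficulty via exhaustive wrapper feature selection over
    a family of standard classifiers with stratified cross-validation. A
    synthetic-data generator emulates the digit-span experimental structure so
    the whole pipeline is testable without access to eye-tracker hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    lme4,
    emmeans,
    e1071,
    MASS,
    rpart,
    ranger,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
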