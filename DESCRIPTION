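Package: percfb
Title: Bayesian Observer Simulation and Cue-Congruence Analysis for
    Corrupted-Feedback Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a Bayesian artificial observer that learns two
    stimulus classes through normal-gamma conjugate beliefs and combines
    sensory evidence with probabilistic cues in a logistic decision rule,
    under experimental sessions in which trial-by-trial feedback is either
    correct or corrupted (half of the labels flipped).  Provides the
    accompanying analysis pipeline for trial-level behavioural data:
    per-run percent correct, the cue congruence index (CCI), session-wise
    linear slopes, and the feedback-type by time linear-contrast
    interaction with partial eta squared.  Includes a synthetic
    behavioural-data generator for testing the pipeline, grating-in-noise
    stimulus synthesis, and a two-phase 2-down-1-up adaptive staircase for
    threshold estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2,
    png
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
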