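Package: defensetrack
Title: Pose-Based Defensive Behavior Classification and Fiber Photometry
    Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies rodent defensive behavior from pose-estimation
    output and processes two-channel fiber photometry recordings.
    Implements velocity-threshold classification of freezing,
    stretch-attend postures, and threat-directed approach and escape
    runs; zone-based scoring of open field, elevated plus maze,
    latency-to-enter, real-time place test, and predator-exposure
    corridor assays; isosbestic-reference correction and z-scoring of
    calcium signals; peri-event averaging and spatial tuning analyses;
    the statistical procedures used with these assays; and a synthetic
    session generator with planted ground truth so every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
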