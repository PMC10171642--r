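Package: softstage
Title: Multi-Scorer Sleep-Stage Fusion, Soft-Consensus Label Smoothing, and
    Calibration Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with multiply-annotated hypnograms: reading and
    validating multi-scorer sleep-stage annotation tables, ranking scorer
    reliability with the Soft-Agreement statistic, building majority-vote and
    soft-consensus references, smoothing one-hot training targets with the
    empirical scorer distribution, and evaluating probabilistic sleep stagers
    with per-subject performance, expected calibration error, and averaged
    cosine similarity against the consensus hypnodensity. Includes a seeded
    simulator for multi-scored sleep databases and a minimal feed-forward
    reference stager for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
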