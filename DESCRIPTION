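Package: actconsensus
Title: Consensus Activity Labels from Thigh-Worn Sensors and Verbal Self-Reports
Version: 0.1.0
Authors@R:
    person("Hardy", "Coleman", email = "hardy.coleman@example.org",
           role = c("aut", "cre"))
Description: Builds minute-level consensus ground-truth activity labels for
    free-living wearable studies with older adults. Converts thigh-worn
    sensor epoch exports into posture labels via the majority-seconds rule,
    estimates personalized cadence thresholds for stepping intensity from
    kernel density peaks, reconstructs activity intervals from verbally
    reported time cues, triangulates the two label sources into consensus
    labels with full shrinkage accounting, and benchmarks a third-party
    activity recognizer (per-class ROC, Youden-optimal thresholds, AUC)
    against each label source. A synthetic multi-source cohort generator
    with configurable posture-confusion, under-reporting and recognizer
    error channels stands in for non-public study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
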