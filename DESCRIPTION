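Package: actisleep
Title: Sleep-Wake Scoring and Benchmarking for Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for epoch-by-epoch sleep-wake scoring of wrist actigraphy
    against polysomnography (PSG) ground truth. Implements the six classical
    count-threshold scoring algorithms (Webster, Cole-Kripke, Sadeh, Oakley,
    Sazonov, Scripps Clinic), Webster's five wake-rescoring rules,
    sliding-window feature extraction and learned classifiers, clinical
    sleep-quality metrics (wake after sleep onset, sleep efficiency), and a
    cohort-level benchmark harness with night and night-and-day evaluation
    tasks. A seeded semi-Markov simulator generates realistic synthetic
    cohorts so the full pipeline is exercisable without access to restricted
    sleep-study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    e1071,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
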