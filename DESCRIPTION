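Package: orphanmcda
Title: Multi-Criteria Decision Analysis for Orphan-Drug Value Assessment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven engine for multi-criteria decision analysis
    (MCDA) of orphan drugs, built around the ten-criterion Emirates value
    framework. Provides criterion scoring functions over ordered categorical
    outcome levels, SMART & Swing weight elicitation from consensus-session
    votes (rank aggregation, criteria-count selection, multiplicative swing
    chains, normalization), additive 0-100 scoring of drug profiles,
    multi-drug comparison, and a three-part concordance validation procedure
    (50-point threshold, rank order, minimum score spread). Criteria sets,
    drug profiles, votes and expectations load from human-editable YAML/JSON
    configs and CSV tables; reports write to CSV, JSON and Markdown, and a
    command-line interface ties the steps together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
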