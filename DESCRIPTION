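Package: sitr
Title: Simulation and Analysis Engine for the Speeded Inference Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, fully testable implementation of the Speeded
    Inference Task (SIT), a four-target, two-rule speeded decision paradigm
    for studying error awareness. Provides balanced trial-plan generation
    with counterbalanced colour-category mappings, constraint-satisfying
    stimulus composition with the task's hierarchical rule semantics, an
    adaptive response-deadline (timeout) algorithm with balanced
    timeout-target pooling, a scoring system, parametric synthetic
    participants, and the behavioural-analysis suite for such experiments:
    response and detection rates, rule-wise splits, stationarity-gated
    post-error slowing, post-error accuracy, post-timeout speeding, and
    rule-misapplication error-source classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
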