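Package: habitcache
Title: Policy Caching and Habit Formation in Discrete Active Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-state active inference agent for a double T-maze
    foraging task, together with three policy-caching schemes that transfer
    control from deliberative planning to habitual action selection.
    Provides the generative model (likelihood, transition, preference and
    prior components), exact belief filtering, expected free energy
    evaluation, precision-weighted softmax policy selection, a delta-rule
    policy cache with threshold-based habitisation, and a batch experiment
    harness with per-trial metrics covering habit formation, perseveration
    after context switches and deliberation cost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
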