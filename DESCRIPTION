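Package: neurogluflow
Title: Event-Locked Striatal Glutamate Transients and Behavioral Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis chain for dual-channel (active/sentinel) fixed-potential
    amperometry of extracellular glutamate recorded during cued treadmill
    behavior, together with the behavioral scoring it depends on. Provides
    in-vitro electrode calibration fits (sensitivity, selectivity, limit of
    detection, linearity) with acceptance criteria, sentinel-channel background
    subtraction, dopamine-response normalization, conversion of net currents to
    micromolar glutamate, event-anchored baseline/cue/reward window extraction,
    a threshold-and-prominence peak detector for cue- and reward-locked
    transients, Pavlovian Conditioned Approach (PCA) indexing with
    sign-/goal-tracker classification, Cued-Triggered Turning Task (CTTT)
    session scoring, and contingency-table analyses of phenotype-specific turn
    probabilities (Fisher exact tests, Koopman asymptotic-score intervals for
    relative probabilities, threshold sweeps, Pearson chi-square). A seeded
    synthetic-data generator emulates calibration series, 5 Hz two-channel
    current traces with event-locked transients, and behavioral session logs,
    so the full pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
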