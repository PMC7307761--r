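Package: ecnsim
Title: Design and Simulation of In-Time, Economically Sustainable Emergency Care Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing emergency care networks (ECNs) in which
    hospitals and points of care collaborate through patient transfers.
    Provides a configurable multi-node emergency-department discrete-event
    simulator with weekday-by-time-slot arrival pipelines, a triage-based
    patient-transfer policy, a collateral payment-settlement engine for
    distributing per-admission utilities between origin and destination
    nodes, six-sigma process-capability diagnostics of waiting times,
    FMEA risk prioritization, and input-analysis utilities (randomness,
    homogeneity and goodness-of-fit testing, arrival partitioning). A
    built-in two-hospital, eight-point-of-care reference network and a
    seeded synthetic-scenario generator make every component testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    nortest,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
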