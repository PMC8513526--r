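Package: napdyn
Title: Automated Patch-Clamp Analysis of Sodium Channel Inhibitor Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing automated patch-clamp recordings of
    voltage-gated sodium currents acquired with a 17-pulse cumulative
    voltage protocol that combines state-dependent-onset, recovery-from-
    inactivation and steady-state-inactivation assays within a single
    1 Hz sweep. Provides the protocol builder and validator, readers and
    writers for sweep-trace, protocol, schedule and peak-amplitude CSV
    files, capacitive-artifact cancellation and peak extraction, ensemble
    quality control, constrained Boltzmann and bi-exponential recovery
    curve fitting with RMSE and relative-error diagnostics and a stepwise
    model-extension procedure, sweep-by-sweep parameter tracking of drug
    wash-in and wash-out macro-kinetics, and a synthetic-experiment
    generator used to validate every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    minpack.lm,
    MASS,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
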