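Package: photodyn
Title: Simulation and Analysis of Noise-Evoked Fiber-Photometry Dynamics
Version: 0.1.0
Authors@R:
    person("photodyn", "developers", email = "photodyn@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing event-aligned fiber-photometry recordings
    from auditory noise-burst experiments: trial-aligned baseline z-scoring,
    per-burst peak/latency response metrics, increase/decrease subject
    phenotype classification, pooled intensity-trend inference with
    subject-level cluster-robust standard errors, studentized wild cluster
    bootstrap-t p-values and test-inversion confidence intervals, plus
    two-compartment avoidance and pupil-response behavioural metrics.
    Includes a synthetic-data generator that emulates ramped/damped
    noise-burst stimulus schedules and the two observed response phenotypes
    with known ground truth, so every analysis stage is testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
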