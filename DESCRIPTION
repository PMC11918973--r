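Package: wardflow
Title: Temporal Dynamics of Ward-Level Nursing Demand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses daily patient-level nursing-demand scores (the 0-12
    activities-of-daily-living/cognition component of the Japanese Intensity of
    Nursing Care Needs instrument) as ward-level state trajectories over an
    18-day post-admission horizon. Provides eligibility filtering and trajectory
    processing for raw patient-day records, day-indexed transition counts and
    proportions over a 15-state space (13 score levels, transfer to other wards
    or specialized beds, and an absorbing discharge state), band-trajectory and
    trajectory-diversity summaries, fixed-layout Sankey diagrams, and a
    day-inhomogeneous absorbing Markov model supporting probabilistic
    forecasting and quantitative cross-ward and cross-year comparison. A
    seeded synthetic-cohort generator with orthopaedic, neurosurgery, and
    cardiology ward archetypes makes the full pipeline testable without
    access to hospital data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
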