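Package: ibddemand
Title: Agent-Based Simulation of Healthcare Demand for Inflammatory Bowel
    Disease Under Disruption Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds region-localized synthetic populations of patients with
    inflammatory bowel disease (IBD) from marginal targets (deterministic
    largest-remainder cell allocation, moment-matched truncated-normal age
    sampling, and linear-programming reweighting of a seed population), and
    runs those weighted patient agents through a weekly clinical-pathway
    state machine (symptom onset, care seeking, diagnosis, continuous care,
    monitoring procedures, biologic maintenance) under time-varying demand
    and supply disruptions with capacity constraints and a backlog queue.
    Includes builders for pandemic-wave, earthquake, and financial-crisis
    scenario modifiers, a catalogue of recovery interventions applied as
    fractional restoration of disrupted multipliers, two-phase calibration
    of pathway and disruption-response parameters against weekly claims
    aggregates by replicate-averaged derivative-free search, a synthetic
    claims-series generator with known ground truth for calibration
    harnesses, ensemble summaries, and CSV/JSON interfaces with a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    pracma,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
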