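Package: ghprofit
Title: Cost Accounting and Net-Profit Evaluation for Autonomous Greenhouse
    Cultivation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates greenhouse cultivation strategies on an economic
    objective, as used in autonomous-greenhouse competition trials of
    dwarf tomato. Computes daily fixed and variable costs (lamp
    electricity under peak/off-peak tariffs, pipe-rail heating, CO2
    dosing) from 5-minute actuator traces, prices the harvested crop with
    a piecewise fruit-value model gated on ripeness and fresh weight,
    assembles the net-profit objective over a plant-density schedule, and
    searches retrospectively for the profit-maximizing harvest date.
    Includes a seeded synthetic-data generator emulating trial-like
    actuator traces and sparse destructive crop observations, so the full
    pipeline is testable without access to trial data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
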