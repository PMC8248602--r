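Package: occmot
Title: Dopamine-Receptor Occupancy and Motivation Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools linking PET-measured dopamine-receptor occupancy to
    benefit- and cost-based motivation in operant tasks. Implements
    simplified reference tissue model (SRTM) estimation of binding
    potential from dynamic PET time-activity curves, receptor occupancy
    via the binding-potential ratio and the Lassen graphical method,
    Hill dose-occupancy and exponential occupancy-decay calibration,
    refusal-rate models of reward-size incentive (inverse model) and
    workload/delay cost discounting (linear model), refusal-rate versus
    reaction-time regression, and BIC-based selection among nested model
    families. A synthetic-data module generates PET and trial-level
    behavioral datasets with known ground truth so every stage is
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
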