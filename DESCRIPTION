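Package: asthmon
Title: Multi-Sensor Home Monitoring of Paediatric Asthma Control
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-week multi-sensor home
    monitoring of children with asthma. Generates synthetic cohorts of
    controlled/uncontrolled asthmatic and non-asthmatic children, renders raw
    sensor streams (single-lead ECG, wrist actigraphy epoch counts, handheld
    spirometry manoeuvres, smart-inhaler event logs), extracts the
    physiological home-monitoring parameters (ECG-derived respiration from the
    RS amplitude, post-exercise heart-rate and respiratory-rate recovery
    times, Cole-Kripke sleep scoring, activity intensity and bout statistics,
    lung-function variability, medication adherence), and classifies asthma
    control with multiple imputation followed by stepwise forward
    likelihood-ratio logistic regression, Nagelkerke R-squared model
    optimisation, pooled odds ratios and diagnostic validity measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
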