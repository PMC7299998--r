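Package: aggkin
Title: Amyloid Aggregation Kinetics and Chaperone Activity Analysis
Version: 0.1.0
Authors@R:
    person("aggkin", "maintainers", email = "aggkin@example.org", role = c("aut", "cre"))
Description: Analysis of protein aggregation kinetics from plate-reader time
    series. Implements the unseeded nucleation-elongation master-equation
    model for amyloid fibril formation (closed-form fibril mass fraction with
    oracle-corrected coefficients and a moment-ODE reference integrator),
    sigmoidal half-time/growth-rate extraction, global multi-concentration
    fits of the combined rate constants sqrt(kn*k+) and sqrt(k+*k2),
    constrained single-rate-constant fits for chaperone inhibition mechanism
    selection, half-time scaling (gamma-exponent) analysis, and dose-response
    analysis of non-fibrillar (turbidity) aggregation suppression. Includes a
    synthetic plate-data generator with known ground truth and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
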