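Package: spiralsort
Title: Design and Analysis of Spiral Inertial-Microfluidic Particle Separation
Version: 0.1.0
Authors@R: person("Analysis", "Toolkit", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for size- and density-based particle separation in
    spiral (curvilinear) inertial-microfluidic channels with rectangular
    cross-sections. Implements the channel flow quantities (hydraulic
    diameter, Reynolds and Dean numbers, Dean velocity), the forces acting
    on suspended particles (inertial lift, Dean drag, centrifugal), four
    size-based focusing-threshold models including a density-corrected
    model with a linear density-coefficient calibration, a bisection
    ("averaging test") procedure that refines a focusing threshold from
    replicated recovery-rate measurements with a Welch t-test decision
    rule, a reduced-order focusing/outlet simulator with particle
    recovery-rate (PRR) analytics, and a seeded synthetic particle
    population generator for regular microspheres and irregular ground
    powders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
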