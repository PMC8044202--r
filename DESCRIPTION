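Package: kinslip
Title: Chemomechanical Coupling Model of Kinesin-8 Walking and Slipping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic chemomechanical coupling model of processive kinesin-8
    (Kip3) motors whose walking on microtubules is interrupted by brief
    stick-slip episodes. Provides closed-form force- and ATP-dependent
    velocities, stepping ratios, slip kinetics and stall-force solvers; a
    recipe that estimates the kinetic parameters from force-velocity data; a
    seeded stochastic trajectory simulator of the same pathway that serves as
    a Monte-Carlo cross-check of every analytic quantity; and a command-line
    interface for curve scans, simulation and synthetic data generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
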