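Package: huetrack
Title: Simulation and Analysis of Parallel Color-Stream Tracking Precision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how attentional resources are shared when
    observers track two continuously changing color streams on an
    iso-luminant hue circle. Generates paired constrained random-walk hue
    trajectories, simulates a two-resource observer with fixed or
    time-alternating precision allocation, resolves the two-target/two-report
    pairing ambiguity, fits a constrained two-component von Mises mixture to
    signed report errors by expectation maximization, validates fits with
    Monte-Carlo and permutation null distributions, and analyzes precision
    time-courses across stimulus-onset asynchronies with Fourier phase
    differences, phase-locking values, and v-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
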