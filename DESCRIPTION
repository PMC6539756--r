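Package: braggloc
Title: Acoustic Localization of the Proton Bragg Peak
Version: 0.1.0
Authors@R:
    person("braggloc", "developers", email = "braggloc@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and acoustic localization of the thermoacoustic
    (ionoacoustic) pulse emitted by a pulsed proton beam stopping in water.
    Implements the Bortfeld analytical depth-dose (Bragg curve) model with
    range straggling via parabolic cylinder functions, a Kirchhoff-integral
    solver for the thermoacoustic pressure at arbitrary sensor positions,
    time-difference-of-arrival (TDOA) estimation by generalized
    cross-correlation, and Gauss-Newton multilateration of the source
    position. Includes seeded study drivers for cube-array simulation
    studies and a synthetic surrogate of a 12-sensor water-tank experiment,
    plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
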