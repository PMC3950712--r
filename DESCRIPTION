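Package: psithermo
Title: Thermodynamics of Pseudouridine-Containing RNA Duplexes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-state van't Hoff analysis of UV melting curves and
    nearest-neighbor free-energy prediction for short RNA duplexes that may
    contain pseudouridine (encoded "P"), G-U wobble pairs and single dangling
    ends. Implements equilibrium melting curves, nonlinear least-squares
    curve fitting, inverse-melting-temperature versus ln(CT/4) regression,
    the 15 percent two-state consistency criterion, nearest-neighbor
    extinction coefficients, free-energy increment arithmetic with
    root-sum-square error propagation, a seeded synthetic melting-data
    generator, and a reference compilation of published duplex
    thermodynamics for pseudouridine pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, minpack.lm
Suggests: testthat (>= 3.0.0), withr, jsonlite, yaml, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
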