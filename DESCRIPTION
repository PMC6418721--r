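Package: langmuir
Title: Analysis of Langmuir Monolayer Isotherms, Polymer Insertion and
    Domain Imaging
Version: 0.1.0
Authors@R:
    person("Film", "Balance", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pressure-area isotherm analysis of insoluble
    monolayers at the air-water interface: feature extraction (lift-off
    area, compressibility modulus, LE-LC transition onset), the
    ideal-mixing additivity rule and excess area of mixing for co-spread
    lipid-polymer films, maximum insertion pressure (exclusion pressure)
    extrapolation from adsorption experiments, biexponential adsorption
    kinetics, and condensed-domain area-fraction analysis of
    epifluorescence micrographs.  Includes seeded equation-of-state
    simulators that generate every input the analyses consume together
    with ground-truth records, and a command-line interface for batch
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
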