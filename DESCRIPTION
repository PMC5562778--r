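Package: estrapbk
Title: Physiologically Based Kinetic Modelling of Estragole Bioactivation
    in Chinese and Caucasian Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits Michaelis-Menten kinetic constants to in vitro liver
    microsomal and S9 incubation data, scales them to whole-liver rates,
    and integrates a six-compartment flow-limited physiologically based
    kinetic (PBK) model describing oral estragole uptake, its five hepatic
    microsomal conversions, and the further glucuronidation, oxidation and
    sulfation of the proximate carcinogen 1'-hydroxyestragole. Bundled
    Chinese and Caucasian parameter sets support inter-ethnic comparison of
    bioactivation and detoxification: dose-response sweeps, normalized
    sensitivity coefficients, fold-difference tables, dose equivalence by
    root finding, and Margin of Exposure arithmetic. A seeded synthetic
    incubation-data generator makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
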