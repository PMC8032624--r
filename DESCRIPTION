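Package: revdosim
Title: PBK-Modeling-Facilitated Reverse Dosimetry for Organophosphate
    Acetylcholinesterase Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds generic 14-compartment physiologically based kinetic (PBK)
    models for the organophosphate pesticide profenofos in rat and human from
    in vitro metabolism parameters, estimates tissue:plasma partition
    coefficients from tissue composition, fits Michaelis-Menten and IC50
    concentration-response curves, translates in vitro acetylcholinesterase
    (AChE) inhibition data into predicted in vivo dose-response curves by
    reverse dosimetry on the unbound blood Cmax, derives benchmark doses
    (BMD10/BMDL10) by model averaging with a parametric bootstrap, and
    quantifies local parameter sensitivity. Includes synthetic-data
    generators that emulate the statistical structure of the underlying
    in vitro assays so every stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
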