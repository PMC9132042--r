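Package: gluptake
Title: Astrocytic Glutamate Uptake Under Extracellular Potassium Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Biophysical modelling and electrophysiology trace analysis for
    astrocytic glutamate uptake. Implements a six-state kinetic scheme of the
    glial glutamate transporter GLT-1 (steady-state and transient solutions,
    transporter current, zero-current reversal glutamate), a Kir4.1/leak
    astrocyte membrane model, and a reduced multi-compartment simulation of a
    transient extracellular K+ hotspot suppressing local uptake current.
    Includes the matching analysis pipeline for astrocyte recordings
    (tail-scaled subtraction to isolate the transporter current, decay-constant
    fitting, train facilitation profiles, slow K+ current measurement) and a
    seeded generator of synthetic recordings with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
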