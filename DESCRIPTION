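Package: entropore
Title: Stochastic Simulation of Substrate Translocation Through Breathing
    Membrane Transporters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the translocation of substrates (nutrients, ions,
    drugs) through a membrane transporter modeled as a periodically
    breathing conical channel. The alternating-access conformational cycle
    is represented by an oscillating cone whose varying cross-section
    induces an entropic (Fick-Jacobs) force on the substrate; a constant
    chemical-gradient force and thermal noise complete an underdamped
    Langevin equation integrated with the Gronbech-Jensen--Farago
    stochastic Velocity-Verlet scheme. Transport rates are estimated from
    first-passage times over trajectory ensembles, swept over the
    dimensionless frequency omega*L^2/D to locate the resonant optimum,
    and mapped back to physical turnover rates. Closed-form
    mean-first-passage-time quadrature oracles validate the simulator in
    every static limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
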