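Package: peatsim
Title: Reaction-Diffusion Simulation and Pattern Analysis of Ombrotrophic Peatlands
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates self-organised vegetation patterning in ombrotrophic
    (rain-fed) peatlands with a four-field reaction-diffusion model coupling
    vascular plant biomass, Sphagnum moss biomass, hydraulic head and nutrient
    availability on a periodic (toroidal) grid, where a Turing instability
    driven by nutrient accumulation generates spots, labyrinths and percolating
    networks. Provides an explicit Euler integrator with conservative
    face-flux transport, toroidal connected-component labelling with
    winding-number percolation detection, regime classification along a
    nutrient-input gradient, percolation critical-exponent fitting, and
    climate-stress and drought experiments with resilience metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
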