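Package: firebeetle
Title: Stochastic Fire and Bark-Beetle Dynamics in Age-Structured Pine Stands
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time stochastic simulator of a well-mixed, monospecific
    serotinous pine stand subject to two interacting disturbances: mountain
    pine beetle (MPB) infestation of mature trees and wildfire driven by a
    fuel-memory kernel. Juveniles move through K age classes before becoming
    susceptible; infested trees pass through two snag years before reopening
    canopy space; fire severity depends on exponentially decaying memory of
    past burns. The package provides the annual update map, trajectory
    simulation with environmental noise, forest-thinning (FTP) and
    controlled-burning (CBP) management protocols, trajectory summaries
    (outbreak maxima, dominant periods via the discrete Fourier transform),
    ensemble averaging, and parameter-plane sweeps over the juvenile and
    adult burning rates, plus YAML configuration, CSV/JSON trajectory I/O
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
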