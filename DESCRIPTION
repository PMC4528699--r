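Package: mitofate
Title: Hybrid Multi-Scale Simulation of Mitophagy-Apoptosis Crosstalk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the competition between Bnip3-mediated mitophagy and
    Bax/MOMP-driven apoptosis signaling across a heterogeneous mitochondrial
    population. Each mitochondrion carries a mass-action ordinary differential
    equation network for Bnip3 dual-domain (LIR/BH3) signaling, Bcl2
    sequestration, tBid-activated Bax, cytochrome c release and caspase-3
    activation. One hundred such agents move on a 20 x 20 lattice with
    diffusing reactive-oxygen-species, tBid and cytochrome-c fields and a
    consumable autophagosome layer, and commit irreversibly to a mitophagy or
    apoptosis phenotype after a fixed decision window. Includes configurable
    autophagosome spatial distributions, organelle mobility toggles, Gaussian
    Bax/Bcl2 population heterogeneity, named scenario presets, ensemble
    summaries and a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
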