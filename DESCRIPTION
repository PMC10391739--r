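Package: nanotherm
Title: Resonant Heat Transfer Analysis for Functionalized Iron Oxide Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-stage computational characterization of heat
    transfer from functionalized maghemite nanoparticles. Stage one models
    wide-angle X-ray total scattering of vacancy-disordered spinel Fe(x)O4
    nanocrystals with the Debye scattering equation, including log-normal
    polydispersity and least-squares refinement of cell, occupancy and size
    parameters. Stage two builds an aminoalkoxysilane-functionalized,
    solvated (111) maghemite slab, generates thermally equilibrated
    harmonic-network trajectories as a classical stand-in for first-principles
    molecular dynamics, and quantifies resonant energy-transfer pathways via
    velocity-velocity autocorrelation and momentum-momentum cross-correlation
    power spectra and their band overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    igraph,
    withr
Config/testthat/edition: 3
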