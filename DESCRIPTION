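Package: nucphase
Title: Multiphase Phase-Field Simulation of Nuclear Chromatin Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the mesoscale liquid organization of the interphase
    nucleus with a multiphase (phase-field) model. Chromosomal territories and
    heterochromatin subtypes evolve by stochastic Allen-Cahn gradient dynamics
    under a Ginzburg-Landau free energy with volume constraints, excluded-volume
    couplings, nuclear-envelope confinement, and lamina adhesion. Includes a
    volumetric analysis suite (droplet labeling, sphericity, radial density
    profiles, centroid-distance distributions) and parameter sweeps that map
    morphology phase diagrams of nuclear architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'grid.R'
    'geometry.R'
    'numerics.R'
    'model.R'
    'dynamics.R'
    'config.R'
    'isosurface.R'
    'droplets.R'
    'morphology.R'
    'nucphase-package.R'
    'parameters.R'
    'profiles.R'
    'snapshots.R'
    'sweep.R'
    'synthetic.R'
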