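Package: stackCT
Title: Stacking Geometry and Charge-Transfer Descriptors for
    Intercalated Photosensitizer/DNA Excited-State Ensembles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-simulation analysis of an intercalated
    photosensitizer/DNA system. Computes stacking-pose descriptors
    (twist angle, shift and slide distances) from multi-model PDB or XYZ
    trajectories, assigns frames to symmetric/rotated configuration
    windows and selects Boltzmann-representative snapshot subsets by
    Metropolis Monte Carlo, derives fragment transition-density
    descriptors (participation ratios, average delocalization length,
    charge-transfer number, hole/electron positions) with a four-way
    classification into monomer, Frenkel exciton, excimer and
    charge-transfer states, and decomposes the density of states and
    absorption spectrum into state-class contributions. A synthetic-data
    generator builds stacked-dimer geometries and excited-state
    ensembles with known ground truth so the whole pipeline is testable
    without molecular-dynamics or quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
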