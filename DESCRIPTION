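Package: mdconverge
Title: Convergence and Conformational-Plasticity Diagnostics for Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess whether a molecular dynamics trajectory has
    converged and how much conformational plasticity the system explores:
    RMSD against a reference structure, the all-to-all RMSD matrix,
    sequential (leader) cluster counting with plateau detection, GROMOS-style
    neighbour clustering, Cartesian-coordinate principal component analysis,
    per-residue RMSF, dihedral-based time-lagged independent component
    analysis (tICA) with k-means representative extraction, and scalar
    distance gauges such as an inter-monomer pore width. Includes a
    synthetic-trajectory generator with planted metastable states, gate
    motions, fluctuation amplitudes and rigid-body corruption so that every
    analysis stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
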