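Package: allokit
Title: Allosteric Pathway and Free-Energy Analysis Toolkit for Molecular Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for allosteric regulation studies of protein
    kinases from molecular-dynamics-style ensembles: trajectory superposition,
    RMSF/RMSD and principal component analysis with block averaging;
    residue-pairwise force difference networks with thresholded cluster
    detection; native-contact occupancy and conservation statistics;
    well-tempered metadynamics with a helicity-type collective variable;
    umbrella-sampling free-energy profiles via the weighted histogram
    analysis method (WHAM) with bootstrap error bands; and conversion of
    binding free energies to dissociation constants for ligand competition
    tables. Ships a toy-physics generator (overdamped Langevin bead chains
    with analytic pair forces and analytic potentials of mean force) so the
    full pipeline is testable end to end without external trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    bio3d,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
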