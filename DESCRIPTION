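Package: c2s
Title: Contact-Map-Based Reconstruction of Protein and Ion-Channel Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs full-atom protein models, monomeric and
    homotetrameric ion channels, from ternary residue-residue contact maps.
    Provides contact-map derivation and perturbation operators (positive-only,
    random reduction, error injection), dummy-loop handling for multi-chain
    maps, a stochastic distance-constraint C-alpha trace reconstructor,
    ideal-geometry backbone completion with rotamer-based side-chain
    placement, C4 symmetry assembly of channel subunits, structural quality
    metrics (Kabsch superposition, global/subset/local RMSD, structure
    diameter, contact density), and a finite-difference Poisson solver for
    pore-axis electrostatic potential profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
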