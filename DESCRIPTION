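Package: loopgrow
Title: Distance-Guided Chain-Growth Sampling of Protein Loop Conformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates ensembles of closed, clash-free protein loop
    conformations by sequential chain-growth Monte Carlo guided by empirical
    end-to-end distance distributions, and ranks them with a loop-specific
    atom-pair distance-dependent statistical potential. Includes
    internal-coordinate geometry (NeRF-style atom placement, analytic
    circle/sphere constructions), two-dimensional Gaussian kernel density
    estimation of anchor-distance pairs with conditional sampling,
    residue-typed backbone and side-chain dihedral frequency tables, an
    analytic tripeptide loop closure, residue-cutoff plus enlarged-ellipsoid
    spatial pruning of energy evaluations, side-chain construction with
    steric-clash resolution, a loop-database builder over PDB structures with
    secondary-structure assignments, and a synthetic-fixture generator so the
    whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
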