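Package: scaffmime
Title: Design of Peptidomimetics on Bridged Polycyclic Carbon Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage computational design of class C peptidomimetics built
    on sp3-rich bridged polycyclic scaffolds. Stage one exhaustively
    enumerates tri- and tetracyclic bridged all-carbon ring systems from
    bicyclic seeds, filters them by conformational strain, decorates them
    with three methyl attachment points, and ranks the resulting skeletons
    by rigid-body superposition of their attachment vectors onto the
    Calpha-Cbeta vectors of a target peptide conformation. Stage two
    converts a chosen carbon skeleton into chemically meaningful scaffolds
    (heteroatoms, unsaturation) with a SMILES-to-SMILES transformer
    encoder-decoder trained on edit-distance-minimised aligned string
    pairs. Includes a synthetic training-corpus generator, generation
    quality metrics (validity, scaffold retention, novelty), and a
    fragment-contribution synthetic accessibility score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp,
    ChemmineOB,
    ChemmineR,
    bio3d
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Open Babel command line tools (obabel, obenergy) for
    3D embedding and strain energies
Config/testthat/edition: 3
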