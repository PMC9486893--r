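Package: allostate
Title: Conformational-Landscape and Kinetic Signatures of Allostery in the
    LDH/MalDH Superfamily
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how a nonallosteric malate dehydrogenase (MalDH)
    can acquire lactate-dehydrogenase-like (LDH) allosteric character.
    Maps sequences onto the normalized (Eventoff) LDH residue numbering,
    classifies catalytic-site signature residues (positions 68, 102, 199,
    246, 250) and exports phylogenetic tree annotations; reads multi-model
    PDB conformer ensembles and computes rigid-body superpositions,
    inter-residue distance series and the alpha2F helix orientation angle;
    turns geometry series into probability distributions with peak
    detection, two-dimensional angle-distance landscapes with R-like/T-like
    state calls, side-chain dihedral substates and mobile-loop open/closed
    states; fits Michaelis-Menten, substrate-inhibition and allosteric
    sigmoidal rate laws to substrate-saturation data with AICc model
    selection; and generates synthetic conformer ensembles, saturation
    curves and sequence-family fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    cluster,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
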