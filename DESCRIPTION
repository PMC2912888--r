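Package: rotapack
Title: Side-Chain Packing with a Four-Distance Knowledge-Based Potential
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives statistical preferences for residue-residue interaction
    geometry from protein structures using a four-distance description of
    side-chain contacts, scores structures with a four-term knowledge-based
    potential (side chain-side chain and side chain-main chain contact terms,
    a rotamer probability term and a linearized Lennard-Jones term), packs
    side chains by Monte Carlo simulated annealing with quenching, ranks
    decoy sets, and evaluates models with side-chain RMSD, chi-angle
    accuracy, normalized RMSD and a contact score. Includes synthetic-data
    generators (toy structures, planted-geometry contact corpora, decoy
    sets, toy rotamer libraries) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
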