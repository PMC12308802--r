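Package: rapa
Title: Rotamer and Protonation Assignment for Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assigns rotamer and protonation states to the ambiguous side
    chains of a protein structure (ASN/GLN amide flips, HIS tautomers and
    flips, SER/THR/TYR hydroxyl directionality, carboxylate acid dyads,
    disulfide detection) by scoring local hydrogen-bond networks with a
    distance-angle energy lookup table and recursively resolving or
    branching until a complete set of unique, energetically degenerate
    configurations is produced, each written out in PDB format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
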