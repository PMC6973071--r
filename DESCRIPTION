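Package: quadfold
Title: Topology and Sugar-Pucker Analysis of G-Quadruplex Structure Ensembles
Version: 0.1.0
Authors@R:
    person("quadfold", "maintainers", email = "quadfold@example.org",
           role = c("aut", "cre"))
Description: Structural analysis of G-quadruplex (G4) nucleic-acid coordinate
    ensembles. Reads multi-model PDB and mmCIF files, computes furanose
    pseudorotation parameters (phase angle P and amplitude tau_m) and
    glycosidic torsion angles, detects guanine tetrads from Hoogsteen
    hydrogen-bond geometry, assembles stacked tetrad layers into G-columns,
    classifies grooves and loops (lateral, diagonal, propeller, V-shaped,
    including zero-nucleotide V-loops), and infers compatible pseudorotamer
    regions from vicinal scalar couplings through Karplus relations. A
    synthetic-structure generator builds furanose rings, nucleotides and
    complete mock quadruplexes from declarative topology specifications so
    that the whole analysis chain is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
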