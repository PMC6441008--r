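Package: gpcrstab
Title: Stability Analysis of GPCR Fusion Constructs from Structure
    Ensembles and Melting Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to rank the conformational and thermal stability of
    G-protein coupled receptor (GPCR) fusion constructs, such as
    receptor-T4 lysozyme complexes, from structure ensembles and circular
    dichroism melting curves.  Provides multi-model PDB input/output with
    named segment maps, Kabsch superposition, domain-decomposed RMSD
    observables including the transform-transfer fusion-domain RMSD, a
    7x7 per-helix RMSD matrix for transmembrane bundle packing,
    Jarvis-Patrick clustering of ensembles with cumulative cluster
    occupancy, side-chain-center contact distances, Hill-sigmoid melting
    temperature fitting of denaturation-fraction curves, box-plot
    statistics with construct stability ranking, and synthetic-data
    generators for helix-bundle ensembles and melting curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
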