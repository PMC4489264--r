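Package: cgnma
Title: Sequence-Aware Coarse-Grained Normal Mode Analysis of Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained elastic network normal mode analysis for protein
    structures with a sequence-aware spring network in which spring constants
    between residues are modulated by atom-type-weighted surface contacts.
    Predicts the effect of single-point mutations on thermal stability through
    vibrational entropy differences, optionally combined linearly with an
    external enthalpic score, and on per-residue flexibility through predicted
    b-factor difference profiles.  Generates uniform, exhaustive, RMSD-bounded
    conformational ensembles from selected normal modes with an automatic
    conformer cap, a visualization-ordered trajectory, and per-mode
    trajectories.  Includes deterministic synthetic structure generators so
    the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    optparse,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
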