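Package: hexscrew
Title: Screw-Axis Geometry of Hexameric Motor ATPase Rings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric analysis of hexameric secretion/pilus motor ATPases
    (PilB/PilT/GspE family). Decomposes a hexamer into its six packing units
    (the N-terminal N2D of one chain with the C-terminal CTD of the
    ring-adjacent chain), measures the rigid-body screw (rise and twist)
    relating consecutive units, classifies each inter-unit interface as open
    or closed with its bound-nucleotide label, and assembles the six
    interfaces into a ring-closure ledger with pucker (boat/saddle/planar)
    classification. Profiles the central channel and its sub-pores, morphs
    between two nucleotide states by linear interpolation, and infers the
    signed rotation of the sub-pores per catalytic step. Includes a
    synthetic-assembly generator with exact ground truth so the whole
    pipeline is testable without crystallographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
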