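Package: zincturn
Title: Retrostructural Analysis of Zinc-Binding CXXHX Alpha-Turn Motifs and
    Metal-Binding Equilibria
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mines zinc-coordinated Cys-X1-X2-His-X3 alpha-turn motifs from
    protein structures, characterizes their backbone and side-chain
    conformations (torsions, rotamer classes, hydrogen bonds, metal-site
    geometry and Lambda/Delta configuration), partitions them with the GROMOS
    neighbor-count clustering algorithm on a fixed atom subset, reconstructs
    idealized C2-symmetric Cys2His2 homodimers, and fits metal-binding
    dissociation constants from direct and competition titrations of
    self-assembling 2:1 peptide-metal complexes.  Includes a synthetic-data
    generator that builds peptide motifs at prescribed torsions and simulates
    titration curves, so the whole pipeline can be exercised without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
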