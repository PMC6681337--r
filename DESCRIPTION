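Package: axialkit
Title: Helical Lattice Modelling of Bacterial Flagellar Axial Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and analysing helical assemblies of bacterial
    flagellar axial proteins (rod, hook, filament). Generates multi-subunit
    assemblies from screw-symmetry parameters (twist per subunit, rise per
    subunit along the 1-start helix), indexes the protofilament lattice and
    its n-start families, recovers symmetry parameters from coordinates,
    performs least-squares rigid-body (Kabsch) superposition and RMSD
    calculation, builds chimeric subunit models by domain-based grafting of
    homolog segments, computes lattice-indexed inter-subunit contact networks
    under a distance cutoff, maps mutation sites into their contact
    environment, and aligns sequences by dynamic programming or by structure.
    A synthetic-data generator emulating the D0 coiled-coil, l-stretch arm and
    D1 body architecture of axial subunits makes every stage testable without
    downloading deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
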