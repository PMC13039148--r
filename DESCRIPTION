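Package: glycofil
Title: Helical Filament Assembly, Glycan Grafting and Steric Shielding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale modelling pipeline for glycosylated helical protein
    filaments such as bacterial type IV pili. Builds filaments from a single
    subunit by screw (twist/rise) symmetry, assembles Cn point-group rings,
    decorates serine attachment sites with idealized O-linked glycan chains,
    grafts conformer ensembles rigidly onto backbone attachment frames, and
    profiles steric accommodation of the grafted conformers against an
    enclosing channel (per-site acceptance fractions, axially binned
    rejection-rate curves, and channel aperture profiles). Includes seeded
    synthetic generators for subunits, conformer libraries and constricted
    channels, and a strict fixed-column PDB subset reader/writer with
    multi-model support.
License: MIT
Encoding: UTF-8
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
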