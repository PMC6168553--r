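Package: helifil
Title: Helical Filament Symmetry Indexing, Refinement and Interface Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for determining and exploiting helical symmetry of
    protein filaments from two-dimensional image data and atomic models.
    Covers helical-parameter arithmetic (twist/rise, pitch/units-per-turn,
    rational repeats and the layer-line selection rule), averaged power
    spectra and layer-line indexing of filament segment stacks, helical
    diffraction simulation (Cochran-Crick-Vand single-radius model) with
    amplitude-correlation grid refinement of pitch and units per turn,
    filament assembly generation from a monomer with rigid-body
    superposition and RMSD, subunit-interface extraction and death-domain
    type I/II/III classification, solution-versus-solid-state chemical
    shift perturbation mapping, and immuno-gold filament-polarity
    statistics. Includes seeded synthetic-data generators for every input
    so the whole chain runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
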