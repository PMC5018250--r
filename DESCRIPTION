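Package: helifil
Title: Helical Filament Cryo-EM Reconstruction and Atomic Filament Model Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale tools for helically symmetric filament cryo-EM:
    synthetic filament data generation (pseudo-atomic subunits, helical
    lattices, CTF-modulated noisy projection segments, two-population
    mixtures), iterative helical real-space reconstruction (IHRSR) with
    helical symmetry search and two-class rise sorting, Fourier shell
    correlation resolution assessment, construction of complete filament
    atomic models from a single subunit via screw transforms, and
    interface, radial-geometry and lumen-electrostatics analysis of the
    resulting assemblies. Developed around the architecture of conjugative
    (F-family) pili: five-start helical filaments of a small alpha-helical
    pilin with a stoichiometric phospholipid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
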