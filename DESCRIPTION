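Package: xlmap
Title: Photo-Crosslinking Mass Spectrometry Mapping, Restraint Filtering
    of Structure Ensembles, and Remodeling Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping zero-length photo-crosslinks (p-benzoyl-
    phenylalanine and benzophenone-maleimide labeled cysteine) between
    proteins and peptides by mass spectrometry: monoisotopic mass calculus
    for modified and crosslinked peptides, in-silico tryptic digestion,
    MS1/MS2 crosslink identification with site localization and
    UV-dependence filtering, conversion of crosslinks into upper-bound
    distance restraints, restraint-based filtering of docked structure
    ensembles with per-residue contact-probability surfaces, and
    reduction of enzyme-assay time courses (NADH-coupled ATPase, single-
    exponential remodeling) to rate constants. Includes seeded simulators
    for every input so the full pipeline is testable without external
    data, and bundles the reference crosslink tables of the ISWI
    chromatin-remodeler study the pipeline was designed around.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
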