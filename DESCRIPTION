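Package: solstab
Title: Automated Design of Protein Variants with Improved Solubility and Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for the simultaneous optimisation of the
    conformational stability and solubility of proteins and antibody fragments.
    Candidate mutation sites are selected from per-residue solubility profiles,
    solvent exposure and evolutionary conservation; substitutions permitted by a
    position-specific scoring matrix (PSSM) built from a multiple sequence
    alignment are scanned singly, scored by a combined Mutation Score, combined
    into multi-mutation designs and shortlisted, with an explicit check for
    structurally interacting mutations. Includes a transparent surrogate
    solubility model and a pluggable stability (ddG) predictor with a CSV table
    adapter, deterministic synthetic-fixture generators (ideal-helix PDB files,
    column-controlled alignments, stratified ddG benchmark tables), and a false
    discovery rate benchmark with resampling significance for phylogenetically
    filtered stability predictions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
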