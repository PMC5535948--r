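Package: snailMT
Title: Metal Speciation and Expression Analysis for Snail Metallothioneins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the metal-binding characterization of
    cysteine-rich metallothioneins from freshwater snails. Computes
    theoretical average masses of apo- and metal-loaded protein species
    (Zn, Cd, Cu, acid-labile sulfide), deconvolutes electrospray
    charge-state envelopes to neutral masses, assigns observed masses to
    metal stoichiometries, analyses Zn-to-Cd displacement titrations and
    their saturation point, derives sulfur-based protein concentrations and
    metal-to-peptide ratios from elemental (ICP-AES style) readouts,
    profiles cysteine architecture and predicted metal capacities, performs
    absolute qPCR quantification and induction statistics, and ships seeded
    synthetic-data generators so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    seqinr,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
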