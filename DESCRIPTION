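Package: inotoscan
Title: Mining Arthropod Sequence Data for the Inotocin Peptide-Receptor Signalling System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering and annotating the inotocin
    (oxytocin/vasopressin-like) peptide precursor and receptor signalling
    system in arthropod protein and transcriptome sequence collections.
    Implements exact affine-gap Smith-Waterman local alignment with
    Karlin-Altschul E-values for candidate discovery, rule-based precursor
    parsing (mature nonapeptide/decapeptide ring, amidation signal grammar,
    cysteine-rich neurophysin framework), motif-anchor classification of
    candidate GPCRs into inotocin-like versus CCAP-like families, a
    deduplicated peptide census with position frequency matrices and
    consensus derivation, presence/absence mapping over a taxonomy with
    Dollo single-gain loss inference, and a labelled synthetic-data
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
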