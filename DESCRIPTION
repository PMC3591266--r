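Package: ptmscape
Title: Coordination of Post-Translational Modifications on Protein Complexes
    and in Dense Sequence Windows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of how four post-translational modification (PTM)
    classes (lysine acetylation, lysine ubiquitination, tyrosine
    phosphorylation and serine/threonine phosphorylation) are coordinated
    across human-style protein complex data and along protein sequences.
    Collates site-level PTM tables onto one representative sequence per
    gene, scores protein complexes for selective PTM accumulation against a
    covariate-controlled annotation-permutation null, quantifies which
    subunits carry the signal with resampling Z-scores, calls dense "PTMi
    spot" regions by 20-residue window density scanning with within-protein
    permutation nulls, and overlays spots with domain, disorder and cancer
    mutation annotations. Includes a synthetic proteome/complex generator
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
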