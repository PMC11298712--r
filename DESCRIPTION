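Package: presqkit
Title: Characterization and Design of Organellar Targeting Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing N-terminal organellar targeting peptides
    (presequences) and designing synthetic ones. Curates mitochondrial and
    chloroplast presequence datasets from homolog-alignment overhangs, computes
    peptide physicochemistry (net charge at a given pH, mean hydrophobicity,
    hydrophobic moment, helical-wheel projections, positional frequency
    matrices), builds consensus-based synthetic presequences with systematic
    arginine-count, arginine-scanning and point-mutant variant series, screens
    proteome N-termini against a query peptide by ungapped substitution-matrix
    scoring, and classifies peptides with an empirically derived rule-based
    mitochondrial-targeting predictor. A synthetic-proteome simulator makes
    every pipeline stage reproducible without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
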