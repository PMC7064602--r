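Package: peplfdr
Title: Group-Specific Local FDR for Proteogenomic Immunopeptidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composite false-discovery-rate control for peptide-spectrum
    matches (PSMs) in proteogenomic HLA immunopeptidomics. Estimates local
    FDR from target/decoy PSM counts on a charge-stratified 3D histogram
    over search-engine scores (XCorr, deltaCn, spScore), with separate
    prior odds for proteome-derived and non-canonical PSM groups, and
    selects the local-FDR threshold that achieves a requested global FDR.
    Includes a stop-to-stop three-frame ORF database builder for expressed
    non-coding transcripts, peptide classification against a canonical
    proteome with I/L equivalence and transposable-element exceptions,
    two-engine PSM intersection, greedy parsimony protein grouping with
    adjusted peptide counts and length-normalized HLA sampling, QC
    statistics (predicted-binder fraction, retention-time vs
    hydrophobicity regression, one-sided variance F-test), and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
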