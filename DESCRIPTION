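Package: ntaq
Title: Quantitative Proteomics of Protein N-Terminal Acetylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for identifying N-terminal acetyltransferase
    (Nat) substrates from quantitative proteomics experiments that compare a
    wild-type and an acetyltransferase-deletion strain by metabolic 15N
    labeling with a label-swap replicate design. Provides ratio
    quantification of 14N/15N MS1 intensities, replicate-consistency
    filtering with a 95% confidence band, in-silico protease digestion
    (trypsin and Lys-N, full and semi-specific), peptide-to-protein terminus
    mapping, classification of N-terminal events by position and Nat-complex
    consensus, NatB substrate calling, amino-acid frequency (logo) matrices,
    chi-square over-representation statistics for predicted kinases and
    subcellular localizations, cross-species conservation scoring of the
    NatB recognition motif over ortholog groups, and a synthetic-data
    generator that emulates the statistical structure of such experiments
    with a ground-truth manifest for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
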