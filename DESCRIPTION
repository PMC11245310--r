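Package: affinomap
Title: Quantitative Affinity Interactomics for SH3 Domain-Proline-Rich Motif Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative affinity interactomics built around the
    holdup assay: closed-form conversion between prey depletion (binding
    intensity) and equilibrium dissociation constants under the single-site
    hyperbolic model, native-holdup mass-spectrometry depletion statistics
    (median normalization, low-intensity imputation, equal-variance t-tests,
    significance calling, cross-experiment recall and affinity correlation),
    titration curve fitting with partial binding activity, proline-rich motif
    (PxxP) discovery in disordered regions with 15-mer peptide design,
    fragmentomic peptide affinity profiling and affinity-weighted specificity
    logos, censoring-aware Euclidean affinity distances for domain variants,
    and pseudocount PSSM scoring of motif conservation depth across taxonomic
    levels. Includes seed-deterministic synthetic-data generators that emulate
    every measurement type so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
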