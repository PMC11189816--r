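Package: neuropepsig
Title: Differential Neuropeptide Secretion Signatures from Peptidomics
    Presence Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for label-free neuropeptidomics of secreted
    peptides. Reads long-format peptide observation tables (PEAKS-style
    exports) and proneuropeptide precursor FASTA, applies identification
    filters (target-decoy FDR, abundance/quality gates, retention-time and
    mass feature-reliability matching), anchors peptides to precursor
    residue coordinates, calls peptide presence through a hierarchical
    technical-replicate / culture-replicate / subject rule, and computes
    differential secretion signatures between disease and control groups
    under stimulated and basal conditions: group and condition Venn
    partitions, per-precursor tallies, residue coverage maps, and pooled
    t-tests on replicate-aggregated abundances. Includes a synthetic-data
    generator with known ground truth for end-to-end validation and a
    Monte-Carlo presence-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
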