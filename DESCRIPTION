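Package: ragdelscan
Title: Cryptic RSS Scanning and RAG-Mediated Deletion Analysis for Leukemia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying focal gene deletions that arise from
    illegitimate RAG-mediated V(D)J recombination in B-cell precursor acute
    lymphoblastic leukemia. Detects and scores candidate (cryptic)
    recombination signal sequences (heptamer/spacer/nonamer motifs), pairs
    them under the 12/23 rule in deletion-forming orientation, decomposes
    deletion-spanning junction sequences into breakpoints, non-templated
    insertions and microhomology, clusters breakpoints into recurrent
    deletion types and minimal hotspot windows, computes 2x2 cohort
    enrichment statistics (chi-square and Fisher's exact test), quantifies
    ChIP-qPCR percent recovery and relative expression (2^-ddCt), and ships
    a synthetic-data generator emulating a two-exon locus, multiclonal
    cohorts and detection channels for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
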