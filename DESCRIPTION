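Package: mutyminer
Title: Motif-Anchored Mining and Functional Statistics for MutY DNA Glycosylase Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and authenticating MutY adenine DNA
    glycosylase homologs in predicted-protein sets from metagenomes.
    Candidates are prefiltered by optimal local alignment with
    Karlin-Altschul E-value statistics, mapped onto an annotated reference
    by a two-part (domain-split) global alignment, and authenticated
    against a catalog of structure-anchored chemical motifs (iron-sulfur
    Cys4 cluster, catalytic Glu/Asp/Asn, DNA-wedge residues, the
    OG-recognition H-x-FSH motif and the L-xxx-P motif). Supporting
    computations include sequence-derived physical properties (molecular
    weight, isoelectric point, a dipeptide thermostability index),
    TPM abundance normalization, KEGG-orthology presence/absence
    inventories, and bootstrap statistics for rifampicin-resistance
    mutation-suppression assays. Seeded synthetic-data generators produce
    candidate pools with planted positives and decoys, count tables, and
    assay plate counts so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
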