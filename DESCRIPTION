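Package: ervcensus
Title: Endogenous Retrovirus Census: Simulation, Annotation, Polymorphism Calling and LTR Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying endogenous retrovirus (ERV) lineage
    expansions in host genomes. Provides a synthetic-data generator that
    plants proviruses of configurable age and population frequency into a
    host reference and emits paired-end alignments with realistic breakpoint
    signatures (soft-clips, discordant mates, stretched inserts); a
    structural provirus annotator (LTR pairs, target site duplications,
    gag/pro/pol/env profiling); a presence/absence caller for reference and
    non-reference ERV loci with tiered filters and soft-clip rescue for
    low-coverage samples; LTR-divergence molecular-clock dating; and
    cohort-level locus-sharing summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
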