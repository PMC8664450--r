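Package: screenmap
Title: Causal Essential-Gene Identification from Whole-Genome Sequencing of
    Complementation Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies causal essential-gene mutations from whole-genome
    sequencing of paired mutant alleles in complementation groups, as in
    balancer-maintained EMS screens for maternal-effect lethal and sterile
    mutants. Provides zygosity classification from allele read fractions,
    variant-effect annotation against gene models (missense, nonsense,
    splice-site, start-loss, frameshift), a four-stage candidate filter
    cascade with a full audit trail, candidate-gene intersection within
    complementation groups with merging and double-mutant detection from
    complementation-test outcomes, corroboration against deficiency
    (deletion) mapping intervals with certain and uncertain boundaries, a
    synthetic EMS-screen simulator with truth tables for end-to-end
    validation, and summary, gene-set overrepresentation, and
    expression-pattern classification utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    vcfR,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
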