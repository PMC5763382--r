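Package: chemobin
Title: Bin-Centric Analysis of Chemostat Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bin-centric analysis of enrichment-culture metagenomes
    and metatranscriptomes. Implements strand-canonical tetranucleotide
    profiling and compositional binning of assembled contigs, completeness and
    contamination scoring of bins from conserved single-copy marker hits,
    coverage-based relative bin abundance with identity filtering of read
    mappings, per-gene relative transcriptional activity with its bin-level
    normalization contract, log2 treatment-response ratios, rank-threshold
    delineation of 16S rRNA clades by hierarchical clustering, and the
    continuous-culture (chemostat) arithmetic of dilution, pulse dosing and
    washout. A seeded synthetic-community generator produces genomes, contigs,
    gene and marker layouts, read mappings and transcript counts with known
    ground truth so that every stage is testable without external sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
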