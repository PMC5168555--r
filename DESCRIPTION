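Package: spliceff
Title: Genome-Wide Splicing Efficiency from Strand-Specific Yeast RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-intron pre-mRNA splicing efficiency at the 5' and
    3' splice junctions from strand-specific single-end RNA-seq alignments
    and a genome annotation. Splice junctions are detected from N-gapped
    (split) reads, read coverage of the single first and last base of each
    annotated intron is counted strand-specifically, and efficiency is the
    ratio of junction-spanning reads (transreads) to intron terminal-base
    coverage, with a read-count confidence threshold. Supports pooling of
    replicates by genotype, relative efficiencies for sample pairs (e.g.
    mutant versus wild type), CSV output tables and scatterplots, plus a
    deterministic simulator of spliced/unspliced alignments with known
    per-gene spliced fractions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    dplyr,
    tidyr,
    tibble,
    readr,
    ggplot2,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
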