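Package: discordia
Title: Gene-Tree Discordance, Pan-Genome and Structural-Variant Analysis for
    Closely Related Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to dissect phylogenetic conflict between nuclear and
    organelle genomes in recently diverged plant lineages.  Implements a
    triplet-based test that separates incomplete lineage sorting from
    introgression by fitting an exponential mixture to gene-tree internal
    branch lengths and applying a BIC difference rule; a multispecies
    coalescent simulator with an optional introgression pulse that provides
    ground truth for the test; windowed extraction and filtering of
    whole-genome alignment matrices; core/softcore/dispensable/private
    classification of orthogroup gene families with pan/core saturation
    curves; parsing and presence/absence intersection filtering of
    seven-type structural-variant tables with proximal-gene annotation; and
    Kimura two-parameter dating of long terminal repeat (LTR)
    retrotransposon insertions.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    graphics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
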