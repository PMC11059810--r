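#!/usr/bin/env Rscript

# Windowed extraction from a whole-genome alignment matrix: simulate a
# four-taxon alignment, cut 1-kb windows separated by 20 kb, drop windows
# with fewer than 10 parsimony-informative sites, and build a
# neighbour-joining tree for each retained window.

suppressPackageStartupMessages({
  library(discordia)
  library(ape)
})

seed <- 7L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

# tree-structured alignment ((A,B),C) plus outgroup O: informative sites
# come from substitutions on the A-B stem shared against C and O
root <- simulate_alignment("root", length = 430000, divergence = 0,
                           seed = seed)[[1]]
ab_anc <- simulate_alignment("ab", divergence = 0.015, seed = seed + 1L,
                             ancestor = root)[[1]]
aln <- c(
  simulate_alignment(c("A", "B"), divergence = 0.005, seed = seed + 2L,
                     ancestor = ab_anc),
  simulate_alignment(c("C"), divergence = 0.02, seed = seed + 3L,
                     ancestor = root),
  simulate_alignment(c("O"), divergence = 0.08, seed = seed + 4L,
                     ancestor = root))
windows <- extract_windows(aln, window_size = 1000, gap_between = 20000)
flt <- filter_windows(windows, min_informative = 10)
cat(sprintf("extracted %d windows; %d retained, %d removed (<10 informative sites)\n",
            length(windows), flt$tally[["retained"]], flt$tally[["removed"]]))

manifest <- data.frame(
  window = seq_along(windows),
  start = vapply(windows, `[[`, numeric(1), "start"),
  end = vapply(windows, `[[`, numeric(1), "end"),
  informative = vapply(windows, `[[`, numeric(1), "informative_count"))
manifest$retained <- manifest$informative >= 10
write.table(manifest, file.path(out_dir, "window_manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

win_dir <- file.path(out_dir, "windows")
dir.create(win_dir, showWarnings = FALSE)
for (w in flt$retained)
  write_alignment(w$seqs, file.path(win_dir, sprintf("window_%d.fa", w$start)))

trees <- lapply(flt$retained, nj_tree)
class(trees) <- "multiPhylo"
write.tree(trees, file.path(out_dir, "window_trees.nwk"))
cat(sprintf("wrote %d neighbour-joining window trees\n", length(trees)),
    "informative-site counts: ")
print(summary(manifest$informative))
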