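#!/usr/bin/env Rscript

# Structural-variant analysis: generate seven-type SV tables for five
# genomes with five planted deletions exclusive to the southern group
# (Pz, Ph, Pm), summarise deletion:insertion excess, run the
# presence/absence candidate filter, and annotate genes within 2 kb of
# each candidate.

suppressPackageStartupMessages(library(discordia))

seed <- 42L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

design <- planted_sv_design(
  genomes = c("Pz", "Ph", "Pm", "apricotA", "apricotB"),
  present_group = c("Pz", "Ph", "Pm"),
  reference_length = c(chr1 = 2e6, chr2 = 1e6),
  background_counts = c(deletion = 180, insertion = 10,
                        tandem_expansion = 12, tandem_contraction = 12,
                        repeat_expansion = 8, repeat_contraction = 8,
                        inversion = 4),
  n_planted = 5, planted_size = 500, jitter = 0)
svs <- generate_sv_tables(design, seed = seed)

for (g in design$genomes)
  write_assemblytics(svs$records[svs$records$genome == g, ],
                     file.path(out_dir, sprintf("svs_%s.bed", g)))

summ <- summarize_svs(svs$records)
write.table(summ$by_genome, file.path(out_dir, "sv_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("deletion:insertion excess, averaged over genomes: %.1f-fold by count, %.1f-fold by bases\n",
            summ$mean_count_ratio, summ$mean_base_ratio))

cand <- candidate_deletions(svs$records, design$present_group,
                            c("apricotA", "apricotB"),
                            min_reciprocal_overlap = 1.0)
cat(sprintf("candidate deletions present in all of {%s} and absent from the apricot group: %d (planted: %d)\n",
            paste(design$present_group, collapse = ","), nrow(cand),
            nrow(svs$planted)))

genes <- simulate_gene_annotation(svs$planted, design$reference_length,
                                  gene_distance = 1000, seed = seed + 1L)
gff <- file.path(out_dir, "genes.gff3")
write_gff3(genes, gff)
ann <- annotate_proximal_genes(cand, gff, max_distance = 2000)
cat(sprintf("genes within 2 kb of a candidate: %d\n", nrow(ann)))
write.table(merge(cand, ann[, c("candidate", "gene_id", "distance")],
                  by.x = 0, by.y = "candidate", all.x = TRUE)[-1],
            file.path(out_dir, "candidate_deletions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
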