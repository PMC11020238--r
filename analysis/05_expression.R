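#!/usr/bin/env Rscript
# Tissue-expression marking (assembled OR RPKM > 1 with quantified
# junctions), tissue-specificity scoring (TSI), specificity classes, and
# tissue clustering on pairwise sharing with dendrogram comparison
# between coding and noncoding transcript sets.

library(txatlas)
SEED <- 101L

sim <- simulate_annotation(sim_config(), seed = SEED)
expr <- simulate_expression(sim, seed = SEED)
cl <- classify_transcripts(sim$ts, sim$genome, sim$homology,
                           sim$coding_potential)

expressed <- mark_expressed(expr$em)
message(sprintf("expressed calls: %d transcript-tissue pairs; %d%% of",
                sum(expressed),
                round(100 * mean(rowSums(expressed) > 1))))
message("  transcripts are expressed in more than one tissue")

tsi <- tsi_table(expr$em$rpkm, expressed)
cls <- classify_specificity(expressed, tsi)
write_tsv_table(merge(tsi, cls, by = "feature_id"), "results/tsi.tsv")
message("specificity classes:")
print(table(cls$class))

sh <- tissue_sharing(expressed)
write_tsv_table(data.frame(tissue = rownames(sh), sh,
                           check.names = FALSE),
                "results/tissue_sharing.tsv")
h_all <- cluster_tissues(sh)
write_dendrogram(h_all, "results/tissues_all.nwk")

coding_tx <- cl$transcripts$transcript_id[
  cl$transcripts$label == "protein_coding"]
nonc_tx <- setdiff(rownames(expressed), coding_tx)
h_cod <- cluster_tissues(tissue_sharing(
  expressed[coding_tx, , drop = FALSE]))
h_non <- cluster_tissues(tissue_sharing(
  expressed[nonc_tx, , drop = FALSE]))
write_dendrogram(h_cod, "results/tissues_coding.nwk")
write_dendrogram(h_non, "results/tissues_noncoding.nwk")
rho <- compare_dendrograms(h_cod, h_non)
message(sprintf(
  "coding vs noncoding tissue dendrograms: cophenetic Spearman %.3f",
  rho))
write_tsv_table(data.frame(comparison = "coding_vs_noncoding",
                           spearman = rho),
                "results/dendrogram_comparison.tsv")
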