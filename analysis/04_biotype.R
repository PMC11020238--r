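#!/usr/bin/env Rscript
# ORF-based biotype classification: representative-ORF selection against
# the protein-homology table, the transcript decision tree
# (protein-coding / NMD / NSD / sncRNA / lncRNA subtypes), gene-level
# labels including pseudogenes, and the bifunctional / PAT gene flags.

library(txatlas)
SEED <- 101L

sim <- simulate_annotation(sim_config(), seed = SEED)
expr <- simulate_expression(sim, seed = SEED)

cl <- classify_transcripts(sim$ts, sim$genome, sim$homology,
                           sim$coding_potential)
write_tsv_table(cl$transcripts, "results/transcript_biotypes.tsv")
write_tsv_table(cl$genes, "results/gene_biotypes.tsv")

message("transcript biotypes:")
print(table(cl$transcripts$label))
message("gene biotypes:")
print(table(cl$genes$label))

tt <- sim$truth$transcripts
m <- merge(cl$transcripts, tt[!tt$polya_artifact,
                              c("transcript_id", "biotype")],
           by = "transcript_id")
message(sprintf("planted-label agreement: %.1f%% (%d/%d)",
                100 * mean(m$label == m$biotype),
                sum(m$label == m$biotype), nrow(m)))

expressed <- mark_expressed(expr$em)
fl <- flag_bifunctional_and_pat(cl$transcripts, expressed)
write_tsv_table(fl$per_tissue, "results/bifunctional_per_tissue.tsv")
write_tsv_table(fl$genes, "results/gene_flags.tsv")
message(sprintf("%d bifunctional genes, %d PAT genes, %d switch genes",
                sum(fl$genes$bifunctional_any), sum(fl$genes$pat_gene),
                sum(fl$genes$switch_gene)))

# biotype labels travel as GTF attributes
out <- sim$ts
out$tx$transcript_biotype <-
  cl$transcripts$label[match(out$tx$transcript_id,
                             cl$transcripts$transcript_id)]
out$tx$gene_biotype <- cl$genes$label[match(out$tx$gene_id,
                                            cl$genes$gene_id)]
write_annotation(out, "results/catalogue_biotyped.gtf")
message("wrote results/catalogue_biotyped.gtf")
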