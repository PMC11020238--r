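#!/usr/bin/env Rscript
# Collapse structurally equivalent transcripts across tissues (15-nt
# junction fuzz, 100-nt border fuzz for unsupported ends), regroup into
# gene models, assign them to the reference annotation, and measure
# gene-border extensions with RAMPAGE/WTTS validation of the extended
# borders.

library(txatlas)
SEED <- 101L

sim <- simulate_annotation(sim_config(), seed = SEED)
ev <- simulate_evidence(sim, seed = SEED)
keep <- !sim$ts$tx$transcript_id %in%
  flag_genomic_polya(sim$ts, sim$genome)
ts <- tx_subset(sim$ts, sim$ts$tx$transcript_id[keep])

col <- collapse_transcripts(ts)
message(sprintf("collapsed %d transcripts into %d representatives",
                nrow(ts$tx), nrow(col$collapsed$tx)))
write_tsv_table(col$groups, "results/collapse_groups.tsv")

genes <- group_into_genes(col$collapsed)
message(sprintf("regrouped into %d gene models",
                length(unique(genes$tx$gene_id))))

asg <- assign_to_annotated_genes(sim$ts, sim$reference)
ann <- unique(asg$predicted_gene)
message(sprintf("%d / %d planted genes match an annotated gene",
                length(ann), length(unique(sim$ts$tx$gene_id))))

ext <- detect_border_extensions(sim$ts, sim$reference, asg)
ext$validated5 <- validate_tss(sim$ts, ev$RAMPAGE,
                               level = "gene")[ext$predicted_gene_id]
ext$validated3 <- validate_tts(sim$ts, ev$WTTS,
                               level = "gene")[ext$predicted_gene_id]
write_tsv_table(ext, "results/border_extensions.tsv")
write_tsv_table(border_extension_summary(ext),
                "results/border_extension_summary.tsv")
message("border extensions by category:")
print(border_extension_summary(ext))
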