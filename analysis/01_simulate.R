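#!/usr/bin/env Rscript
# Generate the synthetic multi-tissue transcript catalogue that every
# later step analyses: genome, transcript models with planted biotypes
# and duplicate groups, trimmed reference annotation, expression,
# evidence tracks, support tables and the trait-QTL table. Everything is
# deterministic under SEED; later scripts regenerate the same objects
# from the same seed rather than deserialising binary state.

library(txatlas)
SEED <- 101L

cfg <- sim_config()
sim <- simulate_annotation(cfg, seed = SEED)
expr <- simulate_expression(sim, seed = SEED)
ev <- simulate_evidence(sim, seed = SEED)
sup <- simulate_support(sim, seed = SEED)
qtl <- simulate_qtl_table(sim, seed = SEED)

dir.create("results", showWarnings = FALSE)
# bulk generated inputs (genome FASTA, GTFs, BEDs) land under scratch/;
# the small derived tables from later steps land under results/
write_simulation(sim, "scratch/sim", expression = expr, evidence = ev,
                 support = sup, qtl = qtl)

tt <- sim$truth$transcripts
message(sprintf("catalogue: %d transcripts in %d genes across %d tissues",
                nrow(sim$ts$tx), length(unique(sim$ts$tx$gene_id)),
                cfg$n_tissues))
message("planted transcript biotypes:")
print(table(tt$biotype[!tt$polya_artifact]))
message(sprintf("plus %d genomic poly(A) artifacts and %d duplicate copies",
                sum(tt$polya_artifact), sum(!tt$is_template &
                                              !grepl("_(se|ri|use)$",
                                                     tt$transcript_id))))
message("wrote scratch/sim/ (GTF, FASTA, BED, TSV, truth JSON)")
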