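#!/usr/bin/env Rscript
# Alternative-splicing event enumeration: the seven local event classes
# plus unique splice site exons (USE), with per-transcript, per-gene and
# per-tissue summaries.

library(txatlas)
SEED <- 101L

sim <- simulate_annotation(sim_config(), seed = SEED)
expr <- simulate_expression(sim, seed = SEED)

events <- enumerate_all_events(sim$ts)
write_tsv_table(events, "results/as_events.tsv")
message("alternative-splicing events by type:")
print(table(events$event_type))

expressed <- mark_expressed(expr$em)
s <- summarize_as(events, sim$ts, expressed)
write_tsv_table(s$transcripts, "results/as_transcripts.tsv")
write_tsv_table(s$genes, "results/as_genes.tsv")
write_tsv_table(s$tissues, "results/as_tissues.tsv")
spliced <- sim$ts$tx$transcript_id[sim$ts$tx$n_exons > 1]
inv <- s$transcripts$in_as_event[
  s$transcripts$transcript_id %in% spliced]
message(sprintf("%d / %d spliced transcripts (%.0f%%) touch an AS event",
                sum(inv), length(inv), 100 * mean(inv)))
as_genes <- s$genes$n_events[s$genes$n_events > 0]
message(sprintf("median %d events per alternatively spliced gene",
                stats::median(as_genes)))
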