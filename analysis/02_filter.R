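#!/usr/bin/env Rscript
# Transcript-level QC: base-coverage and canonical-junction support,
# genomic poly(A) artifact removal, then (after expression marking) the
# single-tissue-unspliced and promoterless single-exon locus rules.

library(txatlas)
SEED <- 101L

sim <- simulate_annotation(sim_config(), seed = SEED)
expr <- simulate_expression(sim, seed = SEED)
ev <- simulate_evidence(sim, seed = SEED)
sup <- simulate_support(sim, seed = SEED)

r_support <- filter_support(sim$ts, sup)
polya <- flag_genomic_polya(sim$ts, sim$genome)
r_polya <- data.frame(
  transcript_id = sim$ts$tx$transcript_id,
  kept = !sim$ts$tx$transcript_id %in% polya,
  failed_rules = ifelse(sim$ts$tx$transcript_id %in% polya,
                        "genomic_polya", ""))
premrna <- flag_premrna(sim$ts, sim$reference)
r_pre <- data.frame(
  transcript_id = sim$ts$tx$transcript_id,
  kept = !sim$ts$tx$transcript_id %in% premrna,
  failed_rules = ifelse(sim$ts$tx$transcript_id %in% premrna,
                        "premrna", ""))
expressed <- mark_expressed(expr$em)
r_locus <- filter_locus_rules(sim$ts, expressed, ev)

report <- combine_filter_reports(r_support, r_polya, r_pre, r_locus)
write_tsv_table(report, "results/filter_report.tsv")

message(sprintf("kept %d / %d transcripts", sum(report$kept),
                nrow(report)))
message("failure reasons:")
print(table(unlist(strsplit(report$failed_rules[!report$kept], ","))))

# sanity: the artifact flags recover exactly the planted artifacts
tt <- sim$truth$transcripts
stopifnot(setequal(polya, tt$transcript_id[tt$polya_artifact]))
message("planted poly(A) artifacts recovered exactly")
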