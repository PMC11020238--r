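#!/usr/bin/env Rscript
# QTL integration: nearest-expressed-gene assignment, per-trait Fisher
# enrichment of a query gene set, the 1,000-permutation trait-similarity
# network (BH 0.05), and the two-tissue axis correlation test.

library(txatlas)
SEED <- 101L

sim <- simulate_annotation(sim_config(), seed = SEED)
qtl <- simulate_qtl_table(sim, seed = SEED)
spans <- gene_spans(sim$ts)

aq <- assign_qtl_genes(qtl$qtl, spans)
write_tsv_table(aq$assignments, "results/qtl_assignments.tsv")
outside <- aq$assignments$distance_nt[aq$assignments$distance_nt > 0]
message(sprintf(
  "%d QTLs assigned; %d inside gene bodies, median outside distance %d bp",
  nrow(aq$assignments), sum(aq$assignments$distance_nt == 0),
  as.integer(stats::median(outside))))

universe <- spans$gene_id
# enrichment of the first trait's gene set across all traits
enr <- qtl_enrichment(aq$assoc[[1L]], aq$assoc, universe)
write_tsv_table(enr, "results/qtl_enrichment.tsv")
message(sprintf("%d traits enriched for the %s gene set (BH < 0.05)",
                sum(enr$enriched), names(aq$assoc)[1L]))

net <- build_trait_network(aq$assoc, universe, n_perm = 1000,
                           seed = SEED)
write_tsv_table(net$tests, "results/trait_similarity_tests.tsv")
write_tsv_table(net$edges, "results/trait_similarity_edges.tsv")
message(sprintf("trait-similarity network: %d significant pairs",
                nrow(net$edges)))
print(net$edges)
planted <- vapply(qtl$similar_pairs, function(p)
  paste(sort(p), collapse = "-"), "")
found <- paste(net$edges$trait_a, net$edges$trait_b, sep = "-")
message(sprintf("planted similar pairs recovered: %d / %d",
                sum(planted %in% found), length(planted)))

ax <- simulate_axis_expression(seed = SEED)
r <- axis_correlation_test(ax$source, ax$target, ax$pool,
                           n_random = 1000, seed = SEED)
message(sprintf(
  "axis test: %.0f%% of 1,000 BH-adjusted p-values below 0.05 (planted shared factor)",
  100 * r$frac_significant))
write_tsv_table(data.frame(adj_p = r$adj_p), "results/axis_adj_p.tsv")
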