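gene_fix <- function() {
  GenomicRanges::GRanges("chr1",
                         IRanges::IRanges(c(100, 3000, 10000),
                                          c(800, 4000, 12000)),
                         strand = "+",
                         gene_id = c("gA", "gB", "gC"))
}

test_that("nearest expressed gene uses boundary gaps with id tie-break", {
  g <- gene_fix()
  # overlap -> distance 0
  expect_equal(nearest_expressed_gene("chr1", 3500, 3600, g),
               list(gene_id = "gB", distance_nt = 0L))
  # between gA (ends 800) and gB (starts 3000): gaps 200 vs 1000
  hit <- nearest_expressed_gene("chr1", 1000, 2000, g)
  expect_equal(hit$gene_id, "gA")
  expect_equal(hit$distance_nt, 200L)
  # exactly equidistant: smaller id wins
  tie <- nearest_expressed_gene("chr1", 1400, 2400, g)
  expect_equal(tie$distance_nt, 600L)
  expect_equal(tie$gene_id, "gA")
  # wrong chromosome
  expect_null(nearest_expressed_gene("chr9", 1, 10, g))
})

test_that("QTL-to-gene assignment builds per-trait gene sets", {
  qtl <- data.frame(trait = c("t1", "t1", "t2"),
                    qtl_id = c("q1", "q2", "q3"), chrom = "chr1",
                    start = c(500, 11000, 2900), end = c(600, 11100, 2950))
  a <- assign_qtl_genes(qtl, gene_fix())
  expect_setequal(a$assoc$t1, c("gA", "gC"))
  expect_equal(a$assoc$t2, "gB")
  expect_equal(a$assignments$distance_nt, c(0L, 0L, 50L))
})

test_that("enrichment equals the explicit hypergeometric tail", {
  set.seed(5)
  universe <- sprintf("u%03d", 1:100)
  for (i in 1:25) {
    K <- sample(5:40, 1); n <- sample(5:40, 1)
    trait_genes <- sample(universe, K)
    gene_set <- sample(universe, n)
    res <- qtl_enrichment(gene_set, list(tr = trait_genes), universe)
    k <- length(intersect(trait_genes, gene_set))
    expect_equal(res$p, brute_hyper_tail(k, K, 100, n), tolerance = 1e-12)
  }
  # degenerate: trait genes = gene set = universe -> p = 1
  res <- qtl_enrichment(universe, list(tr = universe), universe)
  expect_equal(res$p, 1)
  # zero overlap with large expectation: right-sided p near 1
  res0 <- qtl_enrichment(universe[1:50], list(tr = universe[51:100]),
                         universe)
  expect_gt(res0$p, 0.999999)
  expect_error(qtl_enrichment("g", list(tr = "g"), character(0)),
               "empty universe")
})

test_that("permutation similarity p honours its analytic bounds", {
  universe <- sprintf("u%04d", 1:2000)
  set.seed(9)
  a <- sample(universe, 12)
  # identical sets: no draw can beat a maximal overlap
  r <- trait_similarity(a, a, universe, n_perm = 1000)
  expect_equal(r$observed_overlap, 12L)
  expect_equal(r$perm_p, 1 / 1001)
  # disjoint sets: every draw ties or beats zero
  b <- sample(setdiff(universe, a), 12)
  r0 <- trait_similarity(a, b, universe, n_perm = 1000)
  expect_equal(r0$perm_p, 1)
  expect_error(trait_similarity(a, universe, universe[1:5]), "larger")
})

test_that("Monte-Carlo p converges to the hypergeometric tail", {
  universe <- sprintf("u%03d", 1:200)
  a <- universe[1:30]
  b <- c(universe[21:35], universe[101:115])   # overlap 10, size 30
  set.seed(31)
  r <- trait_similarity(a, b, universe, n_perm = 10000)
  analytic <- brute_hyper_tail(10, 30, 200, 30)
  expect_equal(r$observed_overlap, 10L)
  expect_lt(abs(r$perm_p - analytic), 0.02)
})

test_that("BH adjustment matches the step-up definition on a worked example", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.5)
  manual <- rev(cummin(rev(p * 5 / seq_len(5))))
  expect_equal(stats::p.adjust(p, "BH"), manual)
})

test_that("trait network is deterministic and a single trait yields no edges", {
  universe <- sprintf("u%04d", 1:500)
  set.seed(3)
  assoc <- list(t1 = sample(universe, 10), t2 = sample(universe, 10),
                t3 = sample(universe, 10))
  assoc$t2 <- c(assoc$t1[1:8], assoc$t2[1:2])
  n1 <- build_trait_network(assoc, universe, n_perm = 300, seed = 77)
  n2 <- build_trait_network(assoc, universe, n_perm = 300, seed = 77)
  expect_identical(n1, n2)
  expect_true(all(n1$tests$perm_p >= 1 / 301 & n1$tests$perm_p <= 1))
  expect_equal(nrow(build_trait_network(assoc["t1"], universe)$tests), 0L)
})

test_that("axis correlation test separates shared-factor from independent sets", {
  ax <- simulate_axis_expression(n_source = 15, n_target = 25,
                                 n_pool = 150, n_samples = 30,
                                 shared = TRUE, seed = 4)
  r <- axis_correlation_test(ax$source, ax$target, ax$pool,
                             n_random = 200, seed = 4)
  expect_gt(r$frac_significant, 0.95)
  expect_length(r$reference_correlations, 15 * 25)

  ax0 <- simulate_axis_expression(n_source = 15, n_target = 25,
                                  n_pool = 150, n_samples = 30,
                                  shared = FALSE, seed = 5)
  r0 <- axis_correlation_test(ax0$source, ax0$target, ax0$pool,
                              n_random = 200, seed = 5)
  expect_lt(r0$frac_significant, 0.3)

  # no random draws: reference correlations only
  rr <- axis_correlation_test(ax$source, ax$target, ax$pool,
                              n_random = 0)
  expect_null(rr$adj_p)
  expect_error(axis_correlation_test(ax$source[, 1:2, drop = FALSE],
                                     ax$target[, 1:2, drop = FALSE],
                                     ax$pool), "matched samples")
})
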