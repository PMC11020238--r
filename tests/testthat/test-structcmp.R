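test_that("structural equivalence honours junction and border fuzz", {
  base <- list(c(1000, 1200), c(1500, 1700), c(2000, 2300))
  shift_first <- function(d) list(c(1000 - d, 1200), c(1500, 1700),
                                  c(2000, 2300))
  ts <- mk_ts(list(
    list(id = "a", strand = "+", exons = base),
    list(id = "b", strand = "+", exons = shift_first(80)),
    list(id = "c", strand = "+",                      # junction off by 16
         exons = list(c(1000, 1216), c(1500, 1700), c(2000, 2300))),
    list(id = "d", strand = "+",                      # extra exon
         exons = c(base, list(c(2600, 2700)))),
    list(id = "e", strand = "-", exons = base)))
  expect_true(transcripts_equivalent(ts, "a", "b"))
  expect_false(transcripts_equivalent(ts, "a", "c"))
  expect_false(transcripts_equivalent(ts, "a", "d"))
  expect_false(transcripts_equivalent(ts, "a", "e"))   # strand differs
  # symmetry
  expect_equal(transcripts_equivalent(ts, "b", "a"),
               transcripts_equivalent(ts, "a", "b"))
  # border beyond 100 nt breaks unsupported equivalence
  ts2 <- mk_ts(list(list(id = "a", strand = "+", exons = base),
                    list(id = "f", strand = "+",
                         exons = shift_first(101))))
  expect_false(transcripts_equivalent(ts2, "a", "f"))
  # junction off by exactly 15 is still equivalent
  ts3 <- mk_ts(list(list(id = "a", strand = "+", exons = base),
                    list(id = "g", strand = "+",
                         exons = list(c(1000, 1215), c(1500, 1700),
                                      c(2000, 2300)))))
  expect_true(transcripts_equivalent(ts3, "a", "g"))
})

test_that("evidence-supported ends use window overlap, not the 100-nt fuzz", {
  base <- list(c(1000, 1200), c(1500, 1700))
  mk <- function(d, sup) mk_ts(list(
    list(id = "a", strand = "+", exons = base),
    list(id = "b", strand = "+",
         exons = list(c(1000 - d, 1200), c(1500, 1700)))),
    tss_supported = c(a = sup, b = sup))
  # both supported: 40-nt TSS window-overlap tolerance
  expect_true(transcripts_equivalent(mk(40, TRUE), "a", "b"))
  expect_false(transcripts_equivalent(mk(41, TRUE), "a", "b"))
  # unsupported: the 100-nt fuzz applies
  expect_true(transcripts_equivalent(mk(41, FALSE), "a", "b"))
})

test_that("collapse takes the transitive closure and matches the brute-force oracle", {
  # chain a~b (80), b~c (80), a!~c (160): one class of three
  mk_chain <- function(d1, d2) mk_ts(list(
    list(id = "a", strand = "+", exons = list(c(2000, 3000))),
    list(id = "b", strand = "+", exons = list(c(2000 - d1, 3000))),
    list(id = "c", strand = "+", exons = list(c(2000 - d1 - d2, 3000)))))
  ts <- mk_chain(80, 80)
  col <- collapse_transcripts(ts)
  expect_equal(length(unique(col$groups$group)), 1L)
  expect_equal(nrow(col$collapsed$tx), 1L)
  # representative: longest genomic span
  expect_equal(col$collapsed$tx$transcript_id, "c")
  oracle <- brute_closure(ts)
  expect_equal(length(oracle), 1L)

  # larger random set against the oracle
  set.seed(42)
  specs <- list()
  for (g in 1:12) {
    base <- 10000 * g
    n <- sample(1:4, 1)
    for (k in seq_len(n)) {
      d <- sample(0:120, 1)
      specs[[length(specs) + 1]] <- list(
        id = sprintf("g%02d_t%d", g, k), strand = "+",
        exons = list(c(base - d, base + 500), c(base + 800, base + 1000)))
    }
  }
  ts2 <- mk_ts(specs)
  col2 <- collapse_transcripts(ts2)
  oracle2 <- brute_closure(ts2)
  got <- unname(split(col2$groups$transcript_id, col2$groups$group))
  got <- lapply(got, sort)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(oracle2, paste, "", collapse = ","))
})

test_that("collapse is idempotent and invariant to input order", {
  set.seed(7)
  specs <- lapply(1:9, function(i) list(
    id = sprintf("t%02d", i), strand = "+",
    exons = list(c(5000 * (i %% 3) + 1000 + sample(0:60, 1),
                   5000 * (i %% 3) + 2000))))
  ts <- mk_ts(specs)
  col <- collapse_transcripts(ts)
  again <- collapse_transcripts(col$collapsed)
  expect_equal(sort(again$collapsed$tx$transcript_id),
               sort(col$collapsed$tx$transcript_id))
  perm <- tx_subset(ts, rev(ts$tx$transcript_id))
  colp <- collapse_transcripts(perm)
  expect_equal(sort(colp$collapsed$tx$transcript_id),
               sort(col$collapsed$tx$transcript_id))
})

test_that("collapsed representative unions member tissues", {
  ts <- mk_ts(list(
    list(id = "a", strand = "+", exons = list(c(1000, 2000))),
    list(id = "b", strand = "+", exons = list(c(980, 2020))),
    list(id = "c", strand = "+", exons = list(c(1010, 1990)))),
    tissues = c(a = "liver", b = "testis", c = "brain"))
  col <- collapse_transcripts(ts)
  expect_equal(col$collapsed$tx$tissues, "brain,liver,testis")
})

test_that("gene grouping is single-linkage on 1-nt same-strand span overlap", {
  ts <- mk_ts(list(
    list(id = "a", strand = "+", exons = list(c(100, 200))),
    list(id = "b", strand = "+", exons = list(c(200, 300))),   # 1 nt
    list(id = "c", strand = "-", exons = list(c(150, 250))),   # other strand
    list(id = "d", strand = "+", exons = list(c(290, 400))),   # chains via b
    list(id = "e", strand = "+", exons = list(c(1000, 1100)))))
  g <- group_into_genes(ts)
  gid <- stats::setNames(g$tx$gene_id, g$tx$transcript_id)
  expect_equal(gid[["a"]], gid[["b"]])
  expect_equal(gid[["b"]], gid[["d"]])
  expect_false(gid[["a"]] == gid[["c"]])
  expect_false(gid[["a"]] == gid[["e"]])
  expect_equal(length(unique(gid)), 3L)
})

test_that("annotated-gene assignment needs same-strand exon overlap", {
  ref <- mk_ts(list(list(id = "r1", gene = "R1", strand = "+",
                         exons = list(c(1000, 1200), c(2000, 2200)))))
  ts <- mk_ts(list(
    list(id = "p1", gene = "P1", strand = "+",
         exons = list(c(1200, 1300))),            # 1-nt exon overlap
    list(id = "p2", gene = "P2", strand = "+",
         exons = list(c(1300, 1900))),            # intron only
    list(id = "p3", gene = "P3", strand = "-",
         exons = list(c(1000, 1200))),            # wrong strand
    list(id = "p4", gene = "P4", strand = "+",
         exons = list(c(5000, 5200)))))
  asg <- assign_to_annotated_genes(ts, ref)
  expect_equal(asg$predicted_gene, "P1")
  expect_equal(asg$reference_gene, "R1")
  expect_true(asg$primary)
})

test_that("border extensions are strand-aware span arithmetic", {
  ref <- mk_ts(list(
    list(id = "rp", gene = "RP", strand = "+",
         exons = list(c(1001, 2000), c(4001, 5000))),
    list(id = "rm", gene = "RM", strand = "-",
         exons = list(c(101001, 102000), c(104001, 105000)))))
  ts <- mk_ts(list(
    list(id = "pp", gene = "PP", strand = "+",
         exons = list(c(901, 2000), c(4001, 5200))),
    list(id = "pm", gene = "PM", strand = "-",
         exons = list(c(100901, 102000), c(104001, 105200))),
    list(id = "pin", gene = "PIN", strand = "+",
         exons = list(c(1100, 1900)))))
  asg <- assign_to_annotated_genes(ts, ref)
  ext <- detect_border_extensions(ts, ref, asg)
  pp <- ext[ext$predicted_gene_id == "PP", ]
  expect_equal(pp$ext5_nt, 100L)
  expect_equal(pp$ext3_nt, 200L)
  expect_equal(pp$kind, "both")
  pm <- ext[ext$predicted_gene_id == "PM", ]
  expect_equal(pm$ext5_nt, 200L)   # minus strand: 5' is the high end
  expect_equal(pm$ext3_nt, 100L)
  # fully inside the reference: no record
  expect_false("PIN" %in% ext$predicted_gene_id)
  s <- border_extension_summary(ext)
  expect_equal(s$n[s$kind == "both"], 2L)
})

test_that("promoter and border validation windows are strand-oriented", {
  ts <- mk_ts(list(list(id = "p", strand = "+",
                        exons = list(c(10000, 12000))),
                   list(id = "m", strand = "-",
                        exons = list(c(8000, 10000)))))
  # + promoter window [9500, 10100]
  expect_equal(nrow(assign_peaks_to_promoter(
    ts, peaks_gr(list(c(9601, 9650))))), 1L)
  expect_equal(nrow(assign_peaks_to_promoter(
    ts, peaks_gr(list(c(9401, 9450))))), 0L)
  # - promoter window [9900, 10500] anchored at the minus-strand TSS
  hits <- assign_peaks_to_promoter(ts, peaks_gr(list(c(10301, 10400))))
  expect_equal(hits$feature_id, "m")

  # TSS validation: [-30, +10] around the start site
  v <- validate_tss(ts, peaks_gr(list(c(9990, 10005))))
  expect_true(v[["p"]])
  v2 <- validate_tss(ts, peaks_gr(list(c(9941, 9950))))
  expect_false(v2[["p"]])
  # TTS validation: [-10, +165] around the terminal site
  w <- validate_tts(ts, peaks_gr(list(c(12005, 12010))))
  expect_true(w[["p"]])
  expect_false(validate_tts(ts, peaks_gr(list(c(12205, 12300))))[["p"]])
  # minus-strand TTS at 8000: window [7835, 8010]
  expect_true(validate_tts(ts, peaks_gr(list(c(7900, 7950))))[["m"]])
  expect_false(validate_tts(ts, peaks_gr(list(c(8100, 8200))))[["m"]])
})
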