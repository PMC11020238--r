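spliced_fix <- function() {
  mk_ts(list(list(id = "t1", strand = "+",
                  exons = list(c(1, 100), c(201, 300)))),
        tissues = c(t1 = "liver"))
}

sup_fix <- function(cov = 3, reads = 5, canonical = TRUE, overhang = 5) {
  support_tables(
    data.frame(transcript_id = "t1", tissue = "liver",
               min_base_coverage = cov),
    data.frame(chrom = "chr1", strand = "+", intron_start = 101,
               intron_end = 200, tissue = "liver", reads = reads,
               overhang = overhang, canonical = canonical))
}

test_that("coverage rule is inclusive at 3x and junction rules fire", {
  ts <- spliced_fix()
  expect_true(filter_support(ts, sup_fix(cov = 3))$kept)
  r <- filter_support(ts, sup_fix(cov = 2.9))
  expect_false(r$kept)
  expect_equal(r$failed_rules, "low_coverage")
  r2 <- filter_support(ts, sup_fix(canonical = FALSE))
  expect_match(r2$failed_rules, "noncanonical_junction")
  r3 <- filter_support(ts, sup_fix(reads = 0))
  expect_match(r3$failed_rules, "unsupported_junction")
  # reads exist but with too little overhang
  r4 <- filter_support(ts, sup_fix(overhang = 3))
  expect_match(r4$failed_rules, "unsupported_junction")
  # missing coverage entry names the transcript and tissue
  bad <- sup_fix()
  bad$coverage$tissue <- "brain"
  expect_error(filter_support(ts, bad), "t1.*liver")
})

test_that("pre-mRNA flag needs a junction subset plus a retained intron", {
  ref <- mk_ts(list(list(id = "r1", strand = "+",
                         exons = list(c(1, 100), c(201, 300),
                                      c(401, 500), c(601, 700)))))
  # query keeps junctions 1 and 3, retains reference intron 2
  q1 <- mk_ts(list(list(id = "q1", strand = "+",
                        exons = list(c(1, 100), c(201, 500),
                                     c(601, 700)))))
  expect_equal(flag_premrna(q1, ref), "q1")
  # identical junction chain, nothing retained
  q2 <- mk_ts(list(list(id = "q2", strand = "+",
                        exons = list(c(1, 100), c(201, 300),
                                     c(401, 500), c(601, 700)))))
  expect_length(flag_premrna(q2, ref), 0L)
  # unspliced query is exempt even when it covers an intron
  q3 <- mk_ts(list(list(id = "q3", strand = "+",
                        exons = list(c(1, 700)))))
  expect_length(flag_premrna(q3, ref), 0L)
  # opposite strand never matches
  q4 <- mk_ts(list(list(id = "q4", strand = "-",
                        exons = list(c(1, 100), c(201, 500),
                                     c(601, 700)))))
  expect_length(flag_premrna(q4, ref), 0L)
})

test_that("poly(A) run detection honours the 20-A / 1-mismatch rule", {
  expect_true(has_polya_run(paste0(strrep("A", 20), strrep("C", 10))))
  # one mismatch inside the run of 20 still counts
  expect_true(has_polya_run(paste0(strrep("A", 10), "G", strrep("A", 9),
                                   strrep("C", 10))))
  # 18 As max with the mismatch: below threshold
  expect_false(has_polya_run(paste0(strrep("A", 9), "G", strrep("A", 9),
                                    strrep("C", 11))))
  # mismatch may not be terminal
  expect_false(has_polya_run(paste0("G", strrep("A", 19),
                                    strrep("C", 11))))
})

test_that("genomic poly(A) flag is unspliced-only and strand-aware", {
  dn <- paste0(strrep("A", 20), strrep("C", 10))
  chr <- paste0(strrep("C", 100), dn, strrep("C", 100),
                strrep("T", 22), strrep("G", 100))
  # + strand transcript ending at 100 -> window [101,130] has the run
  # - strand transcript starting at 231 -> upstream Ts reverse-complement
  ts <- mk_ts(list(
    list(id = "plus", strand = "+", exons = list(c(41, 100))),
    list(id = "minus", strand = "-", exons = list(c(253, 330))),
    list(id = "clean", strand = "+", exons = list(c(141, 200))),
    list(id = "spliced", strand = "+",
         exons = list(c(21, 60), c(81, 100)))))
  g <- mk_genome(c(chr1 = chr))
  fl <- flag_genomic_polya(ts, g)
  expect_setequal(fl, c("plus", "minus"))
  # window truncation at the chromosome end warns
  ts_end <- mk_ts(list(list(id = "edge", strand = "+",
                            exons = list(c(nchar(chr) - 59,
                                           nchar(chr))))))
  expect_warning(flag_genomic_polya(ts_end, g), "truncated")
})

test_that("locus rules: single-tissue unspliced and promoterless single-exon genes", {
  ts <- mk_ts(list(
    list(id = "u1", gene = "g1", strand = "+",
         exons = list(c(1000, 1400))),
    list(id = "u2", gene = "g2", strand = "+",
         exons = list(c(5000, 5400))),
    list(id = "u3", gene = "g3", strand = "+",
         exons = list(c(9000, 9400))),
    list(id = "s1", gene = "g4", strand = "+",
         exons = list(c(13000, 13200), c(13500, 13700)))))
  expressed <- matrix(c(TRUE, FALSE,    # u1: one tissue
                        TRUE, TRUE,     # u2: two tissues
                        TRUE, TRUE,     # u3
                        TRUE, FALSE),   # s1 spliced: exempt from rule 1
                      ncol = 2, byrow = TRUE,
                      dimnames = list(c("u1", "u2", "u3", "s1"),
                                      c("a", "b")))
  # g1, g2 rescued by H3K4me3; g3 has only CTCF (no rescue)
  ev <- list(H3K4me3 = peaks_gr(list(c(950, 1010), c(4950, 5010))),
             CTCF = peaks_gr(list(c(8950, 9010))))
  rep <- filter_locus_rules(ts, expressed, ev)
  expect_equal(rep$failed_rules[rep$transcript_id == "u1"],
               "single_tissue_unspliced")
  expect_true(rep$kept[rep$transcript_id == "u2"])
  expect_equal(rep$failed_rules[rep$transcript_id == "u3"],
               "single_exon_no_evidence")
  expect_true(rep$kept[rep$transcript_id == "s1"])
})

test_that("filter reports combine as rule unions", {
  a <- data.frame(transcript_id = c("t1", "t2"), kept = c(FALSE, TRUE),
                  failed_rules = c("low_coverage", ""))
  b <- data.frame(transcript_id = c("t1", "t2"), kept = c(FALSE, FALSE),
                  failed_rules = c("premrna", "genomic_polya"))
  m <- combine_filter_reports(a, b)
  expect_equal(m$failed_rules[m$transcript_id == "t1"],
               "low_coverage,premrna")
  expect_false(any(m$kept))
})
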