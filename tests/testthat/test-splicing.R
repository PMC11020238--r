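grid3 <- list(c(100, 200), c(400, 500), c(700, 800))

test_that("canonical skipped exon, retained intron and A5 are detected", {
  se <- mk_ts(list(
    list(id = "t1", gene = "g", strand = "+", exons = grid3),
    list(id = "t2", gene = "g", strand = "+",
         exons = list(c(100, 200), c(700, 800)))))
  ev <- enumerate_events(se, "g", include_use = FALSE)
  expect_equal(ev$event_type, "SE")
  expect_equal(ev$coordinates, "201:400:500:699")
  expect_setequal(strsplit(ev$transcripts, ",")[[1]], c("t1", "t2"))

  ri <- mk_ts(list(
    list(id = "t1", gene = "g", strand = "+",
         exons = list(c(100, 200), c(400, 500))),
    list(id = "t2", gene = "g", strand = "+",
         exons = list(c(100, 500)))))
  ev <- enumerate_events(ri, "g", include_use = FALSE)
  expect_equal(ev$event_type, "RI")
  expect_equal(ev$coordinates, "100:200:400:500")

  a5 <- mk_ts(list(
    list(id = "t1", gene = "g", strand = "+",
         exons = list(c(100, 200), c(400, 500))),
    list(id = "t2", gene = "g", strand = "+",
         exons = list(c(100, 212), c(400, 500)))))   # donor moved 12 nt
  ev <- enumerate_events(a5, "g", include_use = FALSE)
  expect_true("A5" %in% ev$event_type)
  # same structure mirrored to the minus strand becomes A3
  ev_m <- enumerate_events(mirror_ts(a5), "g", include_use = FALSE)
  expect_true("A3" %in% ev_m$event_type)
})

test_that("MX, AF and AL fire on their canonical configurations", {
  mx <- mk_ts(list(
    list(id = "t1", gene = "g", strand = "+",
         exons = list(c(100, 200), c(300, 350), c(700, 800))),
    list(id = "t2", gene = "g", strand = "+",
         exons = list(c(100, 200), c(500, 550), c(700, 800)))))
  ev <- enumerate_events(mx, "g", include_use = FALSE)
  expect_true("MX" %in% ev$event_type)

  af <- mk_ts(list(
    list(id = "t1", gene = "g", strand = "+",
         exons = list(c(100, 150), c(700, 800))),
    list(id = "t2", gene = "g", strand = "+",
         exons = list(c(300, 380), c(700, 800)))))
  ev <- enumerate_events(af, "g", include_use = FALSE)
  expect_equal(ev$event_type, "AF")
  # mirrored, the alternative first exon becomes an alternative last exon
  expect_equal(enumerate_events(mirror_ts(af), "g",
                                include_use = FALSE)$event_type, "AL")
})

test_that("USE needs overlap and fully unshared flanking junctions", {
  use <- mk_ts(list(
    list(id = "t1", gene = "g", strand = "+",
         exons = list(c(10, 50), c(100, 200), c(700, 800))),
    list(id = "t2", gene = "g", strand = "+",
         exons = list(c(10, 40), c(150, 250), c(700, 790)))))
  u <- detect_use(use, "g")
  expect_equal(u$event_type, "USE")
  expect_equal(u$coordinates, "100:200:150:250")

  # sharing the upstream junction disqualifies the pair
  shared <- mk_ts(list(
    list(id = "t1", gene = "g", strand = "+",
         exons = list(c(10, 50), c(100, 200), c(700, 800))),
    list(id = "t2", gene = "g", strand = "+",
         exons = list(c(10, 50), c(100, 250), c(700, 790)))))
  expect_equal(nrow(detect_use(shared, "g")), 0L)

  # non-overlapping internal exons are not USE
  apart <- mk_ts(list(
    list(id = "t1", gene = "g", strand = "+",
         exons = list(c(10, 50), c(100, 200), c(700, 800))),
    list(id = "t2", gene = "g", strand = "+",
         exons = list(c(10, 40), c(300, 400), c(700, 790)))))
  expect_equal(nrow(detect_use(apart, "g")), 0L)

  # terminal exons never qualify
  term <- mk_ts(list(
    list(id = "t1", gene = "g", strand = "+",
         exons = list(c(100, 200), c(700, 800))),
    list(id = "t2", gene = "g", strand = "+",
         exons = list(c(150, 250), c(700, 790)))))
  expect_equal(nrow(detect_use(term, "g")), 0L)
})

test_that("single-transcript and unspliced genes yield no events", {
  ts <- mk_ts(list(
    list(id = "t1", gene = "g1", strand = "+", exons = grid3),
    list(id = "u1", gene = "g2", strand = "+", exons = list(c(1, 500))),
    list(id = "u2", gene = "g2", strand = "+", exons = list(c(1, 400)))))
  expect_equal(nrow(enumerate_events(ts, "g1")), 0L)
  expect_equal(nrow(enumerate_events(ts, "g2")), 0L)
})

test_that("event sets match the exhaustive oracle on random genes", {
  set.seed(11)
  for (rep in 1:20) {
    ts <- random_grid_gene(sample(2:4, 1), gene = "G")
    got <- event_keys(enumerate_events(ts, "G"))
    want <- brute_as_events(ts, "G")
    expect_equal(got, want, info = paste("replicate", rep))
  }
})

test_that("strand mirroring swaps A5/A3 and AF/AL but fixes SE/RI/MX/USE", {
  set.seed(23)
  for (rep in 1:10) {
    ts <- random_grid_gene(sample(2:4, 1), gene = "G")
    fw <- enumerate_events(ts, "G")
    bw <- enumerate_events(mirror_ts(ts), "G")
    cnt <- function(d) {
      tab <- table(factor(d$event_type,
                          c("SE", "RI", "A5", "A3", "MX", "AF", "AL",
                            "USE")))
      as.vector(tab)
    }
    f <- cnt(fw); b <- cnt(bw)
    expect_equal(f[c(1, 2, 5, 8)], b[c(1, 2, 5, 8)])
    expect_equal(f[3], b[4])   # A5 <-> A3
    expect_equal(f[4], b[3])
    expect_equal(f[6], b[7])   # AF <-> AL
    expect_equal(f[7], b[6])
  }
})

test_that("AS summary flags involved transcripts and counts per gene", {
  ts <- mk_ts(list(
    list(id = "t1", gene = "g", strand = "+", exons = grid3),
    list(id = "t2", gene = "g", strand = "+",
         exons = list(c(100, 200), c(700, 800))),
    list(id = "lone", gene = "g2", strand = "+",
         exons = list(c(5000, 5600)))))
  ev <- enumerate_all_events(ts)
  expressed <- matrix(TRUE, 3, 2,
                      dimnames = list(c("t1", "t2", "lone"), c("a", "b")))
  s <- summarize_as(ev, ts, expressed)
  expect_true(all(s$transcripts$in_as_event[s$transcripts$transcript_id
                                            %in% c("t1", "t2")]))
  expect_false(s$transcripts$in_as_event[
    s$transcripts$transcript_id == "lone"])
  expect_equal(s$genes$n_events[s$genes$gene_id == "g"], 1L)
  expect_equal(s$genes$n_events[s$genes$gene_id == "g2"], 0L)
  expect_equal(s$tissues$frac_expressed_tx_in_as, c(2 / 3, 2 / 3))
})
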