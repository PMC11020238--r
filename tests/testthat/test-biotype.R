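# asparagine filler: {A,C} only, so no start codon can form in any frame
codons <- function(n) strrep("AAC", n)

test_that("find_orfs reports maximal ORFs, including stopless ones", {
  s <- paste0("CCCCCC", "ATG", codons(42), "TAA", "CCCCCC")
  orfs <- find_orfs(s, allow_alternative_starts = FALSE)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$length_aa, 43L)      # ATG + 42 codons before the stop
  expect_true(orfs$has_stop)
  expect_equal(orfs$start, 7L)
  expect_equal(orfs$stop_end, 7L + 43L * 3L + 2L)

  expect_equal(nrow(find_orfs("CCCCCCCCCAAA",
                              allow_alternative_starts = FALSE)), 0L)

  nostop <- paste0("CCC", "ATG", codons(10))
  o2 <- find_orfs(nostop, allow_alternative_starts = FALSE)
  expect_equal(nrow(o2), 1L)
  expect_false(o2$has_stop)
  expect_true(is.na(o2$stop_end))
  expect_equal(o2$length_aa, 11L)

  expect_error(find_orfs(""), "empty")
})

test_that("alternative initiation codons extend the start set", {
  s <- paste0("CCC", "CTG", codons(5), "TAA")
  expect_equal(nrow(find_orfs(s, allow_alternative_starts = FALSE)), 0L)
  o <- find_orfs(s, allow_alternative_starts = TRUE)
  expect_equal(o$start_codon[1L], "CTG")
})

test_that("representative ORF selection follows homology then length", {
  s <- paste0(
    "CC", "ATG", codons(60), "TAA",      # longest, starts at 3
    "C", "ATG", codons(40), "TAA",       # middle, has the good hit
    "ATG", codons(20), "TAA")
  orfs <- find_orfs(s, transcript_id = "t",
                    allow_alternative_starts = FALSE)
  expect_equal(nrow(orfs), 3L)
  mid_id <- orfs$orf_id[orfs$length_aa == 41L]
  hom <- data.frame(query_id = mid_id, subject_id = "sp1",
                    evalue = 1e-10, coverage_pct = 80, identity_pct = 96,
                    search_kind = "protein")
  expect_equal(select_representative_orf(orfs, hom)$orf_id, mid_id)
  # hit below coverage threshold is ignored -> longest ORF
  hom$coverage_pct <- 50
  expect_equal(select_representative_orf(orfs, hom)$length_aa, 61L)
  # no homology at all -> longest ORF
  expect_equal(select_representative_orf(orfs, NULL)$length_aa, 61L)
  expect_null(select_representative_orf(orfs[0, ], NULL))
})

# a two-exon transcript whose spliced sequence we control exactly:
# exon1 600 nt + exon2 `last` nt on a synthetic chromosome
two_exon_fixture <- function(spliced, last = 200L) {
  stopifnot(nchar(spliced) == 600L + last)
  chr <- paste0(substr(spliced, 1, 600), strrep("C", 100),
                substr(spliced, 601, 600 + last))
  ts <- mk_ts(list(list(id = "t", strand = "+",
                        exons = list(c(1, 600), c(701, 700 + last)))))
  list(ts = ts, genome = mk_genome(c(chr1 = chr)))
}

test_that("NMD boundary is strict at 50 spliced nt upstream of the last junction", {
  mk <- function(dist) {
    # stop ends at spliced position 600 - dist; ORF length stays > 44 aa
    stop_end <- 600L - dist
    aa <- (stop_end - 10L - 3L) %/% 3L
    start <- stop_end - 3L * aa - 2L
    s <- paste0(strrep("C", start - 1L), "ATG", codons(aa - 1L), "TAA")
    stopifnot(nchar(s) == stop_end)
    s <- paste0(s, strrep("C", 800L - nchar(s)))
    two_exon_fixture(s)
  }
  for (dist in c(60L, 51L)) {
    f <- mk(dist)
    seqs <- tx_seq(f$ts, f$genome)
    rep_orf <- select_representative_orf(find_orfs(seqs[["t"]], "t"))
    expect_equal(classify_transcript(f$ts, "t", rep_orf)$label, "nmd",
                 info = paste("dist", dist))
  }
  for (dist in c(50L, 10L)) {
    f <- mk(dist)
    seqs <- tx_seq(f$ts, f$genome)
    rep_orf <- select_representative_orf(find_orfs(seqs[["t"]], "t"))
    expect_equal(classify_transcript(f$ts, "t", rep_orf)$label,
                 "protein_coding", info = paste("dist", dist))
  }
})

test_that("raising the NMD distance threshold only moves nmd to coding", {
  f <- local({
    stop_end <- 600L - 70L
    aa <- (stop_end - 10L - 3L) %/% 3L
    start <- stop_end - 3L * aa - 2L
    s <- paste0(strrep("C", start - 1L), "ATG", codons(aa - 1L), "TAA")
    two_exon_fixture(paste0(s, strrep("C", 800L - nchar(s))))
  })
  seqs <- tx_seq(f$ts, f$genome)
  rep_orf <- select_representative_orf(find_orfs(seqs[["t"]], "t"))
  labels <- vapply(c(10, 50, 69, 70, 200), function(th)
    classify_transcript(f$ts, "t", rep_orf,
                        params = biotype_params(nmd_dist_nt = th))$label, "")
  expect_equal(labels, c("nmd", "nmd", "nmd", "protein_coding",
                         "protein_coding"))
})

test_that("44-aa boundary is strict and the noncoding branch splits on 200 nt", {
  # exactly 44 aa with a stop: not protein-coding, falls to noncoding
  s44 <- paste0("CC", "ATG", codons(43), "TAA")
  ts <- mk_ts(list(list(id = "t", strand = "+",
                        exons = list(c(1, nchar(s44))))))
  genome <- mk_genome(c(chr1 = s44))
  rep_orf <- select_representative_orf(find_orfs(s44, "t"))
  expect_equal(rep_orf$length_aa, 44L)
  lab <- classify_transcript(ts, "t", rep_orf)$label
  expect_false(lab %in% c("protein_coding", "nmd", "nsd"))
  expect_equal(lab, "sncRNA")   # 137 nt < 200, no miRNA overlap

  # length exactly 200 goes to the lncRNA branch
  ts200 <- mk_ts(list(list(id = "t", strand = "+",
                           exons = list(c(1, 200)))))
  expect_equal(classify_transcript(ts200, "t", NULL)$label,
               "lncRNA_intergenic")
  # under 200 with an external coding-potential call is not sncRNA
  ts150 <- mk_ts(list(list(id = "t", strand = "+",
                           exons = list(c(1, 150)))))
  expect_equal(classify_transcript(ts150, "t", NULL)$label, "sncRNA")
  expect_false(classify_transcript(ts150, "t", NULL,
                                   coding_potential = TRUE)$label ==
                 "sncRNA")
})

test_that("nonstop transcripts with a start but no stop are nsd", {
  s <- paste0(strrep("C", 10), "ATG", codons(80))
  ts <- mk_ts(list(list(id = "t", strand = "+",
                        exons = list(c(1, nchar(s))))))
  rep_orf <- select_representative_orf(find_orfs(s, "t"))
  expect_equal(classify_transcript(ts, "t", rep_orf)$label, "nsd")
})

test_that("lncRNA subtypes follow antisense > sense-intronic > intragenic", {
  # coding gene on + with two exons and one intron [201, 800]
  specs <- list(
    list(id = "cod", gene = "gc", strand = "+",
         exons = list(c(1, 200), c(801, 1100))),
    list(id = "anti", gene = "ga", strand = "-",
         exons = list(c(300, 600))),
    list(id = "si", gene = "gs", strand = "+",
         exons = list(c(250, 700))),
    list(id = "intra", gene = "gi", strand = "+",
         exons = list(c(1050, 1400))),
    list(id = "inter", gene = "gn", strand = "+",
         exons = list(c(11000, 11400))))
  ts <- mk_ts(specs)
  idx <- coding_gene_index(ts, "gc")
  expect_equal(classify_lncrna_subtype(ts, "anti", idx),
               "lncRNA_antisense")
  expect_equal(classify_lncrna_subtype(ts, "si", idx),
               "lncRNA_sense_intronic")
  expect_equal(classify_lncrna_subtype(ts, "intra", idx),
               "lncRNA_intragenic")
  expect_equal(classify_lncrna_subtype(ts, "inter", idx),
               "lncRNA_intergenic")
})

test_that("gene biotypes: coding dominance, pseudogene needs homology", {
  tb <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4", "t5", "t6"),
    gene_id = c("gA", "gA", "gB", "gB", "gC", "gC"),
    label = c("protein_coding", "nmd", "nmd", "nsd",
              "lncRNA_intergenic", "lncRNA_antisense"),
    fired_rule = "", stringsAsFactors = FALSE)
  hom <- data.frame(query_id = "gB", subject_id = "x", evalue = 1e-20,
                    coverage_pct = 95, identity_pct = 98,
                    search_kind = "nucleotide")
  g <- classify_gene(tb, hom)
  expect_equal(g$label[g$gene_id == "gA"], "protein_coding")
  expect_equal(g$label[g$gene_id == "gB"], "pseudogene")
  expect_equal(g$label[g$gene_id == "gC"], "noncoding")
  # without the nucleotide hit, gB is merely noncoding
  g2 <- classify_gene(tb, NULL)
  expect_equal(g2$label[g2$gene_id == "gB"], "noncoding")
  expect_error(classify_gene(tb[0, ], NULL), NA)
})

test_that("bifunctional, PAT-main and switch flags", {
  tb <- data.frame(
    transcript_id = c("c1", "n1", "c2", "n2", "n3"),
    gene_id = c("gA", "gA", "gB", "gB", "gB"),
    label = c("protein_coding", "nmd", "protein_coding", "nmd", "nsd"),
    fired_rule = "", stringsAsFactors = FALSE)
  expressed <- matrix(FALSE, 5, 2,
                      dimnames = list(c("c1", "n1", "c2", "n2", "n3"),
                                      c("fetal", "adult")))
  expressed["c1", ] <- c(TRUE, TRUE)
  expressed["n1", "fetal"] <- TRUE
  expressed["c2", "adult"] <- TRUE          # gB coding only in adult
  expressed[c("n2", "n3"), "fetal"] <- TRUE # gB noncoding-only in fetal
  fl <- flag_bifunctional_and_pat(tb, expressed)
  pa <- fl$per_tissue
  # gA fetal: 1 coding + 1 nmd -> bifunctional, PAT fraction 0.5 not main
  row <- pa[pa$gene_id == "gA" & pa$tissue == "fetal", ]
  expect_true(row$bifunctional)
  expect_false(row$pat_main)
  # gB fetal: 2 PATs of 2 -> pat_main
  expect_true(pa[pa$gene_id == "gB" & pa$tissue == "fetal", "pat_main"])
  gn <- fl$genes
  expect_true(gn$switch_gene[gn$gene_id == "gB"])
  expect_false(gn$switch_gene[gn$gene_id == "gA"])
  expect_true(all(gn$pat_gene))
})
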