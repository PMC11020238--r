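#' Assemble support tables for transcript QC
#'
#' @param coverage Data frame with columns `transcript_id`, `tissue`,
#'   `min_base_coverage` (the minimum per-base read coverage of the
#'   transcript in that tissue; the coverage rule only consumes the
#'   minimum).
#' @param junctions Data frame with columns `chrom`, `strand`,
#'   `intron_start`, `intron_end`, `tissue`, `reads` (spanning reads),
#'   `overhang` (minimum overhang, in nt, of the counted reads on both
#'   sides of the junction), `canonical` (logical).
#' @return List of the two validated tables, class `support_tables`.
#' @export
support_tables <- function(coverage, junctions) {
  stopifnot(all(c("transcript_id", "tissue", "min_base_coverage") %in%
                  names(coverage)),
            all(c("chrom", "strand", "intron_start", "intron_end",
                  "tissue", "reads", "overhang", "canonical") %in%
                  names(junctions)))
  if (any(coverage$min_base_coverage < 0) || any(junctions$reads < 0))
    stop("coverage and junction read counts must be nonnegative")
  structure(list(coverage = coverage, junctions = junctions),
            class = "support_tables")
}

split_tissues <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE),
         function(v) v[nzchar(v)])
}

#' Coverage and splice-junction support filter
#'
#' A transcript is kept iff (i) its minimum per-base coverage is at least
#' `min_coverage` in every tissue it was assembled in, (ii) every one of
#' its splice junctions is canonical, and (iii) every junction is spanned
#' by at least one read with at least `min_overhang` nt on both sides in
#' some tissue where the transcript was assembled.
#'
#' @param ts A `tx_set` (assembled tissues in `ts$tx$tissues`,
#'   comma-joined).
#' @param support A [support_tables()] object.
#' @param min_coverage Minimum per-base coverage fold (default 3,
#'   inclusive).
#' @param min_overhang Minimum junction overhang in nt (default 5).
#' @return Filter report data frame: `transcript_id`, `kept`,
#'   `failed_rules` (comma-joined subset of `low_coverage`,
#'   `unsupported_junction`, `noncanonical_junction`).
#' @export
filter_support <- function(ts, support, min_coverage = 3,
                           min_overhang = 5) {
  stopifnot(inherits(support, "support_tables"))
  cov <- support$coverage
  jn <- support$junctions
  jn <- jn[jn$overhang >= min_overhang, , drop = FALSE]
  cov_key <- paste(cov$transcript_id, cov$tissue, sep = "\r")
  jn_key <- paste(jn$chrom, jn$strand, jn$intron_start, jn$intron_end,
                  jn$tissue, sep = "\r")
  canon_key <- paste(support$junctions$chrom, support$junctions$strand,
                     support$junctions$intron_start,
                     support$junctions$intron_end, sep = "\r")
  canonical <- tapply(support$junctions$canonical, canon_key, any)

  ids <- ts$tx$transcript_id
  tiss <- split_tissues(ts$tx$tissues)
  out <- data.frame(transcript_id = ids, kept = TRUE,
                    failed_rules = "", stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    id <- ids[k]
    fails <- character(0)
    for (tis in tiss[[k]]) {
      i <- match(paste(id, tis, sep = "\r"), cov_key)
      if (is.na(i))
        stop("missing coverage entry for transcript ", id,
             " in tissue ", tis)
      if (cov$min_base_coverage[i] < min_coverage) {
        fails <- c(fails, "low_coverage"); break
      }
    }
    jx <- tx_junctions(ts, id)
    if (nrow(jx)) {
      chrom <- ts$tx[id, "chrom"]; strand <- ts$tx[id, "strand"]
      for (r in seq_len(nrow(jx))) {
        ck <- paste(chrom, strand, jx[r, 1L], jx[r, 2L], sep = "\r")
        can <- canonical[ck]
        if (is.na(can) || !can) {
          fails <- c(fails, "noncanonical_junction"); break
        }
      }
      supported_all <- all(vapply(seq_len(nrow(jx)), function(r) {
        keys <- paste(chrom, strand, jx[r, 1L], jx[r, 2L], tiss[[k]],
                      sep = "\r")
        any(jn$reads[match(keys, jn_key)] >= 1L, na.rm = TRUE)
      }, TRUE))
      if (!supported_all) fails <- c(fails, "unsupported_junction")
    }
    fails <- unique(fails)
    out$kept[k] <- length(fails) == 0L
    out$failed_rules[k] <- paste(fails, collapse = ",")
  }
  out
}

#' Flag likely pre-mRNA transcripts
#'
#' A spliced transcript is flagged when its splice-junction chain is a
#' subset of some same-strand reference transcript's chain and at least
#' one reference intron is fully contained inside one of its exons
#' (a retained intron). Unspliced transcripts are never flagged.
#'
#' @param ts Query `tx_set`.
#' @param reference Reference `tx_set`.
#' @return Character vector of flagged transcript ids.
#' @export
flag_premrna <- function(ts, reference) {
  ref_ids <- reference$tx$transcript_id
  ref_jx <- lapply(ref_ids, function(id) tx_junctions(reference, id))
  names(ref_jx) <- ref_ids
  flagged <- character(0)
  for (id in ts$tx$transcript_id) {
    qjx <- tx_junctions(ts, id)
    if (!nrow(qjx)) next
    qkeys <- paste(qjx[, 1L], qjx[, 2L])
    ex <- tx_exons(ts, id)
    chrom <- ts$tx[id, "chrom"]; strand <- ts$tx[id, "strand"]
    cand <- ref_ids[reference$tx$chrom == chrom &
                      reference$tx$strand == strand]
    for (rid in cand) {
      rjx <- ref_jx[[rid]]
      if (!nrow(rjx)) next
      rkeys <- paste(rjx[, 1L], rjx[, 2L])
      if (!all(qkeys %in% rkeys)) next
      retained <- vapply(seq_len(nrow(rjx)), function(r) {
        any(BiocGenerics::start(ex) <= rjx[r, 1L] &
              BiocGenerics::end(ex) >= rjx[r, 2L])
      }, TRUE)
      if (any(retained)) { flagged <- c(flagged, id); break }
    }
  }
  flagged
}

# TRUE when `s` contains a run of >= min_a characters, at most
# max_mismatch of them non-A, starting and ending with A.
has_polya_run <- function(s, min_a = 20L, max_mismatch = 1L) {
  ch <- strsplit(toupper(s), "")[[1L]]
  n <- length(ch)
  if (n < min_a) return(FALSE)
  isa <- ch == "A"
  mm <- cumsum(!isa)
  for (i in seq_len(n - min_a + 1L)) {
    j <- i + min_a - 1L
    bad <- mm[j] - if (i > 1L) mm[i - 1L] else 0L
    if (bad <= max_mismatch && isa[i] && isa[j]) return(TRUE)
  }
  FALSE
}

#' Flag unspliced transcripts with a genomic poly(A) stretch
#'
#' Single-exon transcripts whose strand-oriented `window`-bp genomic
#' region immediately 3' of the terminal site contains a stretch of at
#' least `min_a` adenines allowing `max_mismatch` mismatches (the run
#' must start and end with A) are flagged as internally primed genomic
#' DNA artifacts. Windows running past a chromosome end are truncated
#' with a warning.
#'
#' @param ts A `tx_set`.
#' @param genome Named `DNAStringSet`.
#' @param window Downstream window size in bp (default 30).
#' @param min_a Minimum run length (default 20).
#' @param max_mismatch Allowed non-A characters in the run (default 1).
#' @return Character vector of flagged transcript ids.
#' @export
flag_genomic_polya <- function(ts, genome, window = 30L, min_a = 20L,
                               max_mismatch = 1L) {
  flagged <- character(0)
  single <- ts$tx[ts$tx$n_exons == 1L, , drop = FALSE]
  for (k in seq_len(nrow(single))) {
    chrom <- single$chrom[k]
    if (!chrom %in% names(genome))
      stop("chromosome absent from genome: ", chrom)
    clen <- length(genome[[chrom]])
    tts <- single$tts[k]
    if (single$strand[k] == "+") {
      s <- tts + 1L; e <- tts + window
      if (e > clen) { warning("poly(A) window truncated at chromosome end")
        e <- clen }
      if (s > e) next
      win <- as.character(Biostrings::subseq(genome[[chrom]], s, e))
    } else {
      s <- tts - window; e <- tts - 1L
      if (s < 1L) { warning("poly(A) window truncated at chromosome start")
        s <- 1L }
      if (s > e) next
      win <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(genome[[chrom]], s, e)))
    }
    if (has_polya_run(win, min_a, max_mismatch))
      flagged <- c(flagged, single$transcript_id[k])
  }
  flagged
}

#' Locus-level noise filters
#'
#' Removes (i) unspliced transcripts expressed in exactly one tissue and
#' (ii) single-exon genes with no H3K4me3, H3K4me1, H3K27ac or ATAC peak
#' assigned to their promoter (all of the gene's transcripts are removed
#' with it). CTCF and other tracks do not rescue a single-exon gene.
#'
#' @param ts A `tx_set`.
#' @param expressed Logical matrix, transcripts x tissues, from
#'   [mark_expressed()].
#' @param promoter_evidence Named list of `GRanges` evidence tracks
#'   (names are track labels).
#' @param rescue_tracks Tracks whose promoter peaks rescue a single-exon
#'   gene.
#' @param up,down Promoter window around the gene start site (bp).
#' @return Filter report data frame: `transcript_id`, `kept`,
#'   `failed_rules` (subset of `single_tissue_unspliced`,
#'   `single_exon_no_evidence`).
#' @export
filter_locus_rules <- function(ts, expressed, promoter_evidence,
                               rescue_tracks = c("H3K4me3", "H3K4me1",
                                                 "H3K27ac", "ATAC"),
                               up = 500L, down = 100L) {
  ids <- ts$tx$transcript_id
  out <- data.frame(transcript_id = ids, kept = TRUE, failed_rules = "",
                    stringsAsFactors = FALSE)
  n_tis <- rowSums(expressed[ids, , drop = FALSE])
  unspliced <- ts$tx$n_exons == 1L
  r1 <- unspliced & n_tis == 1L

  # single-exon genes: all transcripts unspliced
  by_gene <- split(seq_along(ids), ts$tx$gene_id)
  se_genes <- names(by_gene)[vapply(by_gene, function(i)
    all(ts$tx$n_exons[i] == 1L), TRUE)]
  rescued <- character(0)
  if (length(se_genes)) {
    gtab <- do.call(rbind, lapply(se_genes, function(g) {
      i <- by_gene[[g]]
      strand <- ts$tx$strand[i[1L]]
      gs <- min(ts$tx$start[i]); ge <- max(ts$tx$end[i])
      data.frame(gene_id = g, chrom = ts$tx$chrom[i[1L]], strand = strand,
                 tss = if (strand == "+") gs else ge,
                 stringsAsFactors = FALSE)
    }))
    prom <- GenomicRanges::GRanges(
      gtab$chrom, .anchor_window(gtab$tss, gtab$strand, up, down))
    for (tr in intersect(rescue_tracks, names(promoter_evidence))) {
      pk <- promoter_evidence[[tr]]
      if (!length(pk)) next
      pk2 <- pk; BiocGenerics::strand(pk2) <- "*"
      hit <- GenomicRanges::countOverlaps(prom, pk2) > 0
      rescued <- union(rescued, gtab$gene_id[hit])
    }
  }
  r2_genes <- setdiff(se_genes, rescued)
  r2 <- ts$tx$gene_id %in% r2_genes

  for (k in seq_along(ids)) {
    fails <- c(if (r1[k]) "single_tissue_unspliced",
               if (r2[k]) "single_exon_no_evidence")
    out$kept[k] <- length(fails) == 0L
    out$failed_rules[k] <- paste(fails, collapse = ",")
  }
  out
}

#' Merge filter reports
#'
#' @param ... Filter report data frames over the same transcripts.
#' @return One report; a transcript is kept iff kept in every input, and
#'   `failed_rules` is the union.
#' @export
combine_filter_reports <- function(...) {
  reps <- list(...)
  base <- reps[[1L]][, "transcript_id", drop = FALSE]
  base$kept <- TRUE
  base$failed_rules <- ""
  for (r in reps) {
    i <- match(base$transcript_id, r$transcript_id)
    add <- r$failed_rules[i]
    add[is.na(add)] <- ""
    merged <- mapply(function(a, b) {
      u <- unique(c(strsplit(a, ",")[[1L]], strsplit(b, ",")[[1L]]))
      paste(u[nzchar(u)], collapse = ",")
    }, base$failed_rules, add)
    base$failed_rules <- unname(merged)
  }
  base$kept <- !nzchar(base$failed_rules)
  base
}
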