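#' Fuzzy structural-equivalence parameters
#'
#' @param junction_fuzz Maximum per-boundary splice-junction shift in nt
#'   (default 15).
#' @param border_fuzz Maximum 5'/3' border difference in nt for ends
#'   without evidence support (default 100).
#' @param tss_window_span,tts_window_span Tolerance for two
#'   evidence-supported ends: supported ends are compatible when their
#'   evidence windows overlap, i.e. the TSSs (TTSs) differ by at most the
#'   window span (41 nt for the TSS window from -30 to +10, 176 nt for
#'   the TTS window from -10 to +165; both defaults stated inclusive of
#'   the anchor base).
#' @return List of parameters.
#' @export
equivalence_params <- function(junction_fuzz = 15L, border_fuzz = 100L,
                               tss_window_span = 40L,
                               tts_window_span = 175L) {
  stopifnot(junction_fuzz >= 0L, border_fuzz >= 0L)
  list(junction_fuzz = junction_fuzz, border_fuzz = border_fuzz,
       tss_window_span = tss_window_span,
       tts_window_span = tts_window_span)
}

#' Structural equivalence of two transcripts
#'
#' Two transcripts are structurally equivalent when they lie on the same
#' chromosome and strand, their splice-junction chains have equal length
#' with every intron boundary within `junction_fuzz` nt, and their
#' borders agree: an end supported by evidence in both transcripts must
#' have overlapping evidence windows, any other end may differ by at most
#' `border_fuzz` nt.
#'
#' @param ts A `tx_set` containing both transcripts (border-support flags
#'   in `ts$tx$tss_supported` / `tts_supported`).
#' @param id_a,id_b Transcript ids.
#' @param params [equivalence_params()].
#' @return `TRUE` or `FALSE`.
#' @export
transcripts_equivalent <- function(ts, id_a, id_b,
                                   params = equivalence_params()) {
  a <- ts$tx[id_a, ]; b <- ts$tx[id_b, ]
  if (a$chrom != b$chrom || a$strand != b$strand) return(FALSE)
  ja <- tx_junctions(ts, id_a); jb <- tx_junctions(ts, id_b)
  if (nrow(ja) != nrow(jb)) return(FALSE)
  if (nrow(ja) &&
      (any(abs(ja[, 1L] - jb[, 1L]) > params$junction_fuzz) ||
       any(abs(ja[, 2L] - jb[, 2L]) > params$junction_fuzz)))
    return(FALSE)
  end_ok <- function(pos_a, pos_b, sup_a, sup_b, span) {
    if (sup_a && sup_b) abs(pos_a - pos_b) <= span
    else abs(pos_a - pos_b) <= params$border_fuzz
  }
  end_ok(a$tss, b$tss, a$tss_supported, b$tss_supported,
         params$tss_window_span) &&
    end_ok(a$tts, b$tts, a$tts_supported, b$tts_supported,
           params$tts_window_span)
}

#' Merge transcript sets from several sources
#'
#' @param sets Named list of `tx_set` objects; names are source labels
#'   prefixed to transcript ids when `prefix_ids` is `TRUE`.
#' @param prefix_ids Prefix ids with the source label to keep them unique.
#' @return One `tx_set`.
#' @export
merge_tx_sets <- function(sets, prefix_ids = FALSE) {
  stopifnot(length(sets) >= 1L)
  grs <- list(); txs <- list()
  for (nm in names(sets)) {
    s <- sets[[nm]]
    ex <- s$exons; tx <- s$tx
    if (prefix_ids) {
      ex$transcript_id <- paste(nm, ex$transcript_id, sep = ".")
      tx$transcript_id <- paste(nm, tx$transcript_id, sep = ".")
      tx$gene_id <- paste(nm, tx$gene_id, sep = ".")
    }
    grs[[nm]] <- ex; txs[[nm]] <- tx
  }
  ex <- suppressWarnings(do.call(c, unname(grs)))
  tx <- do.call(rbind, txs)
  rownames(tx) <- tx$transcript_id
  o <- order(tx$transcript_id)
  tx <- tx[o, , drop = FALSE]
  ex <- ex[order(ex$transcript_id, BiocGenerics::start(ex))]
  structure(list(exons = ex, tx = tx), class = "tx_set")
}

# union-find with path compression
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
.uf_union <- function(parent, i, j) {
  ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Collapse structurally equivalent transcripts
#'
#' Partitions the input by the transitive closure of
#' [transcripts_equivalent()] (union-find over all candidate pairs) and
#' keeps one representative per class: the member with the longest
#' genomic span, ties broken by lexicographically smallest transcript id.
#' The representative's tissue set is the union over class members.
#' Output is invariant to input order.
#'
#' @param ts A `tx_set` (e.g. from [merge_tx_sets()]).
#' @param params [equivalence_params()].
#' @return List with `collapsed` (a `tx_set` of representatives) and
#'   `groups` (data frame: `transcript_id`, `group`, `representative`).
#' @export
collapse_transcripts <- function(ts, params = equivalence_params()) {
  tx <- ts$tx[order(ts$tx$transcript_id), , drop = FALSE]
  ids <- tx$transcript_id
  n <- length(ids)
  parent <- .uf_new(n)
  # candidate buckets: equivalence requires same chrom/strand and equal
  # junction-chain length
  njx <- tx$n_exons - 1L
  bucket <- split(seq_len(n), paste(tx$chrom, tx$strand, njx))
  for (idx in bucket) {
    if (length(idx) < 2L) next
    for (i in idx) for (j in idx[idx > i]) {
      if (.uf_find(parent, i) == .uf_find(parent, j)) next
      if (transcripts_equivalent(ts, ids[i], ids[j], params))
        parent <- .uf_union(parent, i, j)
    }
  }
  root <- vapply(seq_len(n), function(i) .uf_find(parent, i), 0L)
  groups <- split(seq_len(n), root)
  span <- tx$end - tx$start + 1L
  rep_of <- vapply(groups, function(g) {
    g[order(-span[g], ids[g])][1L]
  }, 0L)
  gmap <- data.frame(transcript_id = ids,
                     group = match(root, as.integer(names(groups))),
                     stringsAsFactors = FALSE)
  gmap$representative <- ids[rep_of[gmap$group]]

  keep_ids <- ids[rep_of]
  collapsed <- tx_subset(ts, keep_ids)
  # union of member tissues per class
  for (g in seq_along(groups)) {
    members <- ids[groups[[g]]]
    u <- sort(unique(unlist(split_tissues(tx[members, "tissues"]))))
    collapsed$tx[ids[rep_of[g]], "tissues"] <- paste(u, collapse = ",")
    collapsed$tx[ids[rep_of[g]], "tss_supported"] <-
      any(tx[members, "tss_supported"])
    collapsed$tx[ids[rep_of[g]], "tts_supported"] <-
      any(tx[members, "tts_supported"])
  }
  list(collapsed = collapsed, groups = gmap)
}

#' Group transcripts into putative gene models
#'
#' Single-linkage clustering of same-chromosome, same-strand transcripts
#' whose spans overlap by at least one nucleotide; each connected
#' component becomes one gene, renamed `PG<k>` in positional order, and
#' `gene_id` is rewritten on the returned set.
#'
#' @param ts A `tx_set`.
#' @param prefix Gene id prefix (default `"PG"`).
#' @return A `tx_set` with regrouped `gene_id`s.
#' @export
group_into_genes <- function(ts, prefix = "PG") {
  tx <- ts$tx
  n <- nrow(tx)
  if (n == 0L) return(ts)
  spans <- GenomicRanges::GRanges(tx$chrom,
                                  IRanges::IRanges(tx$start, tx$end),
                                  strand = tx$strand)
  hits <- GenomicRanges::findOverlaps(spans, spans, minoverlap = 1L)
  parent <- .uf_new(n)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (k in seq_along(qh))
    if (qh[k] < sh[k]) parent <- .uf_union(parent, qh[k], sh[k])
  root <- vapply(seq_len(n), function(i) .uf_find(parent, i), 0L)
  comp_start <- tapply(tx$start, root, min)
  comp_chrom <- tapply(tx$chrom, root, function(x) x[1L])
  ord <- order(comp_chrom, comp_start)
  new_id <- stats::setNames(
    sprintf("%s%05d", prefix, seq_along(ord)),
    names(comp_start)[ord])
  out <- ts
  out$tx$gene_id <- unname(new_id[as.character(root)])
  i <- match(out$exons$transcript_id, out$tx$transcript_id)
  if (!is.null(out$exons$gene_id)) out$exons$gene_id <- out$tx$gene_id[i]
  out
}

#' Gene spans of a tx_set
#' @param ts A `tx_set`.
#' @return `GRanges` with one range per gene (`gene_id` metadata).
#' @export
gene_spans <- function(ts) {
  tx <- ts$tx
  agg <- unique(tx[, c("gene_id", "chrom", "strand")])
  s <- tapply(tx$start, tx$gene_id, min)[agg$gene_id]
  e <- tapply(tx$end, tx$gene_id, max)[agg$gene_id]
  GenomicRanges::GRanges(agg$chrom,
                         IRanges::IRanges(as.integer(s), as.integer(e)),
                         strand = agg$strand, gene_id = agg$gene_id)
}

#' Assign predicted genes to annotated reference genes
#'
#' A predicted gene belongs to an annotated gene when at least one of its
#' exons overlaps a reference gene's exons by at least one nucleotide on
#' the same strand. All hit references are kept; the one with the largest
#' total exonic overlap is marked primary.
#'
#' @param ts Predicted `tx_set`.
#' @param ref Reference `tx_set`.
#' @return Data frame: `predicted_gene`, `reference_gene`, `overlap_bp`,
#'   `primary`. Predicted genes with no row are unannotated.
#' @export
assign_to_annotated_genes <- function(ts, ref) {
  pex <- ts$exons
  pgene <- ts$tx$gene_id[match(pex$transcript_id, ts$tx$transcript_id)]
  rex <- ref$exons
  rgene <- ref$tx$gene_id[match(rex$transcript_id, ref$tx$transcript_id)]
  hits <- GenomicRanges::findOverlaps(pex, rex, minoverlap = 1L)
  if (!length(hits))
    return(data.frame(predicted_gene = character(0),
                      reference_gene = character(0),
                      overlap_bp = integer(0), primary = logical(0)))
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(pex)[S4Vectors::queryHits(hits)],
    IRanges::ranges(rex)[S4Vectors::subjectHits(hits)]))
  d <- data.frame(predicted_gene = pgene[S4Vectors::queryHits(hits)],
                  reference_gene = rgene[S4Vectors::subjectHits(hits)],
                  ov = ov, stringsAsFactors = FALSE)
  agg <- stats::aggregate(ov ~ predicted_gene + reference_gene, d, sum)
  names(agg)[3L] <- "overlap_bp"
  agg <- agg[order(agg$predicted_gene, -agg$overlap_bp,
                   agg$reference_gene), , drop = FALSE]
  agg$primary <- !duplicated(agg$predicted_gene)
  rownames(agg) <- NULL
  agg
}

#' Detect gene-border extensions over a reference annotation
#'
#' For each predicted gene and its primary reference gene, computes the
#' strand-aware 5' and 3' span extensions (0 when the predicted border
#' lies inside the reference span) and categorises them as 5'-only,
#' 3'-only or both-ends extended. Predicted genes fully inside their
#' reference yield no record.
#'
#' @param ts Predicted `tx_set`.
#' @param ref Reference `tx_set`.
#' @param assignment Output of [assign_to_annotated_genes()].
#' @return Data frame: `predicted_gene_id`, `reference_gene_id`, `kind`
#'   (`five_prime` / `three_prime` / `both`), `ext5_nt`, `ext3_nt`.
#' @export
detect_border_extensions <- function(ts, ref, assignment) {
  prim <- assignment[assignment$primary, , drop = FALSE]
  ps <- gene_spans(ts); rs <- gene_spans(ref)
  rows <- list()
  for (k in seq_len(nrow(prim))) {
    p <- ps[ps$gene_id == prim$predicted_gene[k]]
    r <- rs[rs$gene_id == prim$reference_gene[k]]
    strand <- as.character(BiocGenerics::strand(p))
    if (strand == "+") {
      ext5 <- max(0L, BiocGenerics::start(r) - BiocGenerics::start(p))
      ext3 <- max(0L, BiocGenerics::end(p) - BiocGenerics::end(r))
    } else {
      ext5 <- max(0L, BiocGenerics::end(p) - BiocGenerics::end(r))
      ext3 <- max(0L, BiocGenerics::start(r) - BiocGenerics::start(p))
    }
    if (ext5 == 0L && ext3 == 0L) next
    kind <- if (ext5 > 0L && ext3 > 0L) "both"
    else if (ext5 > 0L) "five_prime" else "three_prime"
    rows[[length(rows) + 1L]] <- data.frame(
      predicted_gene_id = prim$predicted_gene[k],
      reference_gene_id = prim$reference_gene[k],
      kind = kind, ext5_nt = ext5, ext3_nt = ext3,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(predicted_gene_id = character(0),
                      reference_gene_id = character(0),
                      kind = character(0), ext5_nt = integer(0),
                      ext3_nt = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise border extensions per category
#' @param ext Output of [detect_border_extensions()].
#' @return Data frame: `kind`, `n`, `median_ext5_nt`, `median_ext3_nt`.
#' @export
border_extension_summary <- function(ext) {
  if (!nrow(ext))
    return(data.frame(kind = character(0), n = integer(0),
                      median_ext5_nt = numeric(0),
                      median_ext3_nt = numeric(0)))
  do.call(rbind, lapply(split(ext, ext$kind), function(d) data.frame(
    kind = d$kind[1L], n = nrow(d),
    median_ext5_nt = stats::median(d$ext5_nt[d$ext5_nt > 0]),
    median_ext3_nt = stats::median(d$ext3_nt[d$ext3_nt > 0]),
    stringsAsFactors = FALSE)))
}

# anchor positions of features at transcript or gene level
.feature_anchors <- function(ts, level = c("transcript", "gene"),
                             anchor = c("tss", "tts")) {
  level <- match.arg(level); anchor <- match.arg(anchor)
  if (level == "transcript") {
    data.frame(feature_id = ts$tx$transcript_id, chrom = ts$tx$chrom,
               strand = ts$tx$strand, pos = ts$tx[[anchor]],
               stringsAsFactors = FALSE)
  } else {
    gs <- gene_spans(ts)
    strand <- as.character(BiocGenerics::strand(gs))
    pos <- if (anchor == "tss")
      ifelse(strand == "+", BiocGenerics::start(gs), BiocGenerics::end(gs))
    else
      ifelse(strand == "+", BiocGenerics::end(gs), BiocGenerics::start(gs))
    data.frame(feature_id = gs$gene_id,
               chrom = as.character(GenomeInfoDb::seqnames(gs)),
               strand = strand, pos = pos, stringsAsFactors = FALSE)
  }
}

.window_overlap <- function(anchors, peaks, up, down) {
  win <- GenomicRanges::GRanges(
    anchors$chrom, .anchor_window(anchors$pos, anchors$strand, up, down))
  pk <- peaks
  if (length(pk)) BiocGenerics::strand(pk) <- "*"
  GenomicRanges::findOverlaps(win, pk, minoverlap = 1L)
}

#' Assign evidence peaks to promoters
#'
#' The promoter spans from `up` bp 5' to `down` bp 3' of the feature
#' start site (strand-aware); a peak overlapping it by at least one
#' nucleotide is assigned.
#'
#' @param ts A `tx_set`.
#' @param peaks `GRanges` evidence track.
#' @param up,down Window in bp (defaults 500 and 100).
#' @param level `"transcript"` or `"gene"`.
#' @return Data frame: `feature_id`, `peak_index`.
#' @export
assign_peaks_to_promoter <- function(ts, peaks, up = 500L, down = 100L,
                                     level = "transcript") {
  anchors <- .feature_anchors(ts, level, "tss")
  hits <- .window_overlap(anchors, peaks, up, down)
  data.frame(feature_id = anchors$feature_id[S4Vectors::queryHits(hits)],
             peak_index = S4Vectors::subjectHits(hits),
             stringsAsFactors = FALSE)
}

#' Validate transcript/gene start sites against RAMPAGE peaks
#'
#' A start site is supported when at least one peak overlaps the
#' strand-oriented window from `up` bp 5' to `down` bp 3' of it.
#'
#' @param ts A `tx_set`.
#' @param rampage `GRanges` of RAMPAGE peaks.
#' @param up,down Window in bp (defaults 30 and 10).
#' @param level `"transcript"` or `"gene"`.
#' @return Named logical vector over features.
#' @export
validate_tss <- function(ts, rampage, up = 30L, down = 10L,
                         level = "transcript") {
  anchors <- .feature_anchors(ts, level, "tss")
  hits <- .window_overlap(anchors, rampage, up, down)
  out <- rep(FALSE, nrow(anchors))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  stats::setNames(out, anchors$feature_id)
}

#' Validate transcript/gene terminal sites against WTTS-seq reads
#'
#' @param ts A `tx_set`.
#' @param wtts `GRanges` of WTTS-seq read intervals.
#' @param up,down Window in bp (defaults 10 and 165).
#' @param level `"transcript"` or `"gene"`.
#' @return Named logical vector over features.
#' @export
validate_tts <- function(ts, wtts, up = 10L, down = 165L,
                         level = "transcript") {
  anchors <- .feature_anchors(ts, level, "tts")
  hits <- .window_overlap(anchors, wtts, up, down)
  out <- rep(FALSE, nrow(anchors))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  stats::setNames(out, anchors$feature_id)
}
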