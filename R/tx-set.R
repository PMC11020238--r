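#' Transcript set container
#'
#' A `tx_set` bundles the exon structures of a collection of transcript
#' models with per-transcript metadata. Exons live in a
#' [GenomicRanges::GRanges] carrying a `transcript_id` metadata column;
#' transcript-level fields (gene assignment, provenance, strand-aware TSS
#' and TTS, border-support flags) are derived into a data frame. All
#' coordinates are 1-based closed, the native GenomicRanges convention.
#'
#' @param exons A `GRanges` of exons with a `transcript_id` metadata column
#'   and optionally `gene_id`. Strand must be `+` or `-`.
#' @param gene_id Optional named character vector mapping transcript_id to
#'   gene_id; overrides any `gene_id` column.
#' @param tissues Optional named character vector (comma-joined tissue
#'   names per transcript).
#' @param dataset Provenance label, one of `"rnaseq"`, `"isoseq"`, `"ont"`,
#'   `"ensembl_ref"`, `"ncbi_ref"`; scalar or named per-transcript vector.
#' @param tss_supported,tts_supported Optional named logical vectors of
#'   border-evidence flags (default `FALSE`).
#'
#' @return An object of class `tx_set` with elements `exons` (sorted
#'   `GRanges`) and `tx` (one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `n_exons`, `tss`, `tts`,
#'   `dataset`, `tissues`, `tss_supported`, `tts_supported`).
#' @export
tx_set <- function(exons, gene_id = NULL, tissues = NULL,
                   dataset = "rnaseq",
                   tss_supported = NULL, tts_supported = NULL) {
  stopifnot(methods::is(exons, "GRanges"))
  if (is.null(exons$transcript_id))
    stop("exons must carry a 'transcript_id' metadata column")
  if (any(BiocGenerics::start(exons) < 1))
    stop("exon start < 1: coordinates are 1-based closed")
  str <- as.character(BiocGenerics::strand(exons))
  if (any(str == "*"))
    stop("transcript exons must be stranded (+ or -)")

  o <- order(exons$transcript_id, BiocGenerics::start(exons))
  exons <- exons[o]
  tid <- exons$transcript_id

  chrom_by <- tapply(as.character(GenomeInfoDb::seqnames(exons)), tid,
                     function(x) x[1L])
  if (any(tapply(as.character(GenomeInfoDb::seqnames(exons)), tid,
                 function(x) length(unique(x))) > 1L))
    stop("all exons of a transcript must share one chromosome")
  strand_by <- tapply(as.character(BiocGenerics::strand(exons)), tid,
                      function(x) x[1L])
  if (any(tapply(as.character(BiocGenerics::strand(exons)), tid,
                 function(x) length(unique(x))) > 1L))
    stop("all exons of a transcript must share one strand")

  st <- BiocGenerics::start(exons); en <- BiocGenerics::end(exons)
  ok_gap <- tapply(seq_along(exons), tid, function(i) {
    if (length(i) == 1L) return(TRUE)
    all(st[i][-1L] - en[i][-length(i)] >= 2L)   # introns >= 1 bp
  })
  if (!all(unlist(ok_gap)))
    stop("exons of a transcript must be non-overlapping with introns >= 1 bp")

  ids <- names(chrom_by)
  span_start <- as.integer(tapply(st, tid, min))
  span_end <- as.integer(tapply(en, tid, max))
  n_ex <- as.integer(tapply(st, tid, length))
  strand_v <- as.character(strand_by)

  gid <- if (!is.null(gene_id)) {
    unname(gene_id[ids])
  } else if (!is.null(exons$gene_id)) {
    as.character(tapply(as.character(exons$gene_id), tid, function(x) x[1L]))
  } else ids
  gid[is.na(gid)] <- ids[is.na(gid)]

  pick <- function(x, default) {
    if (is.null(x)) return(rep(default, length(ids)))
    x <- stats::setNames(as.vector(x), names(x))
    if (is.null(names(x))) return(rep(x, length.out = length(ids)))
    out <- unname(x[ids]); out[is.na(out)] <- default; out
  }

  tx <- data.frame(
    transcript_id = ids,
    gene_id = gid,
    chrom = as.character(chrom_by),
    strand = strand_v,
    start = span_start,
    end = span_end,
    n_exons = n_ex,
    tss = ifelse(strand_v == "+", span_start, span_end),
    tts = ifelse(strand_v == "+", span_end, span_start),
    dataset = pick(dataset, "rnaseq"),
    tissues = pick(tissues, ""),
    tss_supported = pick(tss_supported, FALSE),
    tts_supported = pick(tts_supported, FALSE),
    stringsAsFactors = FALSE
  )
  rownames(tx) <- tx$transcript_id
  structure(list(exons = exons, tx = tx), class = "tx_set")
}

#' @export
print.tx_set <- function(x, ...) {
  cat(sprintf("tx_set: %d transcripts, %d genes, %d exons\n",
              nrow(x$tx), length(unique(x$tx$gene_id)), length(x$exons)))
  invisible(x)
}

#' @export
length.tx_set <- function(x) nrow(x$tx)

#' Subset a tx_set by transcript ids
#' @param ts A `tx_set`.
#' @param ids Character vector of transcript ids to keep.
#' @return A `tx_set` restricted to `ids`.
#' @export
tx_subset <- function(ts, ids) {
  keep <- ts$exons$transcript_id %in% ids
  out <- ts
  out$exons <- ts$exons[keep]
  out$tx <- ts$tx[ts$tx$transcript_id %in% ids, , drop = FALSE]
  out
}

#' Exons of one transcript
#' @param ts A `tx_set`.
#' @param id Transcript id.
#' @return `GRanges` of that transcript's exons, sorted by start.
#' @export
tx_exons <- function(ts, id) ts$exons[ts$exons$transcript_id == id]

#' Introns of all transcripts
#'
#' @param ts A `tx_set`.
#' @return `GRanges` of introns (gaps between consecutive exons), with
#'   `transcript_id` metadata; empty for unspliced transcripts.
#' @export
tx_introns <- function(ts) {
  ex <- ts$exons
  tid <- ex$transcript_id
  idx <- split(seq_along(ex), tid)
  parts <- lapply(idx, function(i) {
    if (length(i) < 2L) return(NULL)
    s <- BiocGenerics::start(ex)[i]; e <- BiocGenerics::end(ex)[i]
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(ex))[i[1L]],
               start = e[-length(e)] + 1L, end = s[-1L] - 1L,
               strand = as.character(BiocGenerics::strand(ex))[i[1L]],
               transcript_id = tid[i[1L]], stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) {
    gr <- GenomicRanges::GRanges()
    gr$transcript_id <- character(0)
    return(gr)
  }
  d <- do.call(rbind, parts)
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                         strand = d$strand, transcript_id = d$transcript_id)
}

#' Intron chain of one transcript as a coordinate matrix
#'
#' @param ts A `tx_set`.
#' @param id Transcript id.
#' @return Integer matrix with columns `start`, `end` (one row per intron,
#'   genomic order); zero rows for unspliced transcripts.
#' @export
tx_junctions <- function(ts, id) {
  ex <- tx_exons(ts, id)
  if (length(ex) < 2L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  s <- BiocGenerics::start(ex); e <- BiocGenerics::end(ex)
  cbind(start = e[-length(e)] + 1L, end = s[-1L] - 1L)
}

#' Spliced (mature) transcript lengths
#' @param ts A `tx_set`.
#' @return Named integer vector of summed exon lengths.
#' @export
spliced_length <- function(ts) {
  w <- BiocGenerics::width(ts$exons)
  out <- tapply(w, ts$exons$transcript_id, sum)
  stats::setNames(as.integer(out), names(out))[ts$tx$transcript_id]
}

#' Spliced sense sequence of each transcript
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' minus-strand transcripts, yielding the mature sense-strand sequence.
#'
#' @param ts A `tx_set`.
#' @param genome Named [Biostrings::DNAStringSet] keyed by chromosome.
#' @return `DNAStringSet` named by transcript id.
#' @export
tx_seq <- function(ts, genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  ids <- ts$tx$transcript_id
  seqs <- lapply(ids, function(id) {
    ex <- tx_exons(ts, id)
    chr <- as.character(GenomeInfoDb::seqnames(ex))[1L]
    if (!chr %in% names(genome))
      stop("chromosome absent from genome: ", chr)
    pieces <- Biostrings::DNAStringSet(genome[[chr]],
                                       start = BiocGenerics::start(ex),
                                       end = BiocGenerics::end(ex))
    s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
    if (as.character(BiocGenerics::strand(ex))[1L] == "-")
      s <- Biostrings::reverseComplement(s)
    s
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

# Strand-aware genomic window around an anchor position: `up` bases to the
# 5' side and `down` bases to the 3' side of the anchor, truncated at 1.
.anchor_window <- function(pos, strand, up, down) {
  s <- ifelse(strand == "+", pos - up, pos - down)
  e <- ifelse(strand == "+", pos + down, pos + up)
  s[s < 1L] <- 1L
  IRanges::IRanges(s, e)
}
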