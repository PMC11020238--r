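#' Read transcript models from a GTF file
#'
#' Imports exon features from an Ensembl-dialect GTF (1-based closed
#' coordinates, native to this package) and assembles them into a
#' [tx_set]. `transcript_biotype`, `gene_biotype` and `source_tissues`
#' attributes are carried through when present.
#'
#' @param path Path to a GTF file.
#' @return A `tx_set`. An empty file yields an empty set with a warning.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  body <- raw[!grepl("^#", raw) & nzchar(trimws(raw))]
  if (!length(body)) {
    warning("empty annotation file: ", path)
    return(empty_tx_set())
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   stop("GTF parse error in ", path, ": ",
                        conditionMessage(e)))
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) {
    warning("no exon features in: ", path)
    return(empty_tx_set())
  }
  if (is.null(gr$transcript_id) || is.null(gr$gene_id))
    stop("GTF exons must carry gene_id and transcript_id attributes")
  first_by_tx <- function(x) {
    v <- tapply(as.character(x), gr$transcript_id, function(y) y[1L])
    stats::setNames(as.character(v), names(v))
  }
  tiss <- NULL
  if (!is.null(gr$source_tissues)) {
    tiss <- first_by_tx(gr$source_tissues)
    tiss[is.na(tiss)] <- ""
  }
  ds <- "rnaseq"
  if (!is.null(gr$source)) {
    src <- first_by_tx(gr$source)
    if (all(src %in% c("rnaseq", "isoseq", "ont", "ensembl_ref",
                       "ncbi_ref")))
      ds <- src
  }
  keep <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(gr),
    IRanges::ranges(gr),
    strand = BiocGenerics::strand(gr),
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id)
  )
  ts <- tx_set(keep, tissues = tiss, dataset = ds)
  if (!is.null(gr$transcript_biotype)) {
    bt <- first_by_tx(gr$transcript_biotype)
    ts$tx$transcript_biotype <- unname(bt[ts$tx$transcript_id])
  }
  if (!is.null(gr$gene_biotype)) {
    gb <- first_by_tx(gr$gene_biotype)
    ts$tx$gene_biotype <- unname(gb[ts$tx$transcript_id])
  }
  ts
}

empty_tx_set <- function() {
  gr <- GenomicRanges::GRanges()
  gr$transcript_id <- character(0)
  structure(list(
    exons = gr,
    tx = data.frame(transcript_id = character(0), gene_id = character(0),
                    chrom = character(0), strand = character(0),
                    start = integer(0), end = integer(0),
                    n_exons = integer(0), tss = integer(0),
                    tts = integer(0), dataset = character(0),
                    tissues = character(0), tss_supported = logical(0),
                    tts_supported = logical(0), stringsAsFactors = FALSE)
  ), class = "tx_set")
}

#' Write transcript models to a GTF file
#'
#' Emits one exon feature per exon with `gene_id` and `transcript_id`
#' attributes; biotype labels (if present in `ts$tx$transcript_biotype` /
#' `gene_biotype`) and comma-joined `source_tissues` are written as GTF
#' attributes so that [read_annotation()] round-trips losslessly.
#'
#' @param ts A `tx_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ts, path) {
  ex <- ts$exons
  tx <- ts$tx
  i <- match(ex$transcript_id, tx$transcript_id)
  gr <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(ex), IRanges::ranges(ex),
    strand = BiocGenerics::strand(ex))
  gr$source <- tx$dataset[i]
  gr$type <- "exon"
  gr$gene_id <- tx$gene_id[i]
  gr$transcript_id <- ex$transcript_id
  if (any(nzchar(tx$tissues))) gr$source_tissues <- tx$tissues[i]
  if (!is.null(tx$transcript_biotype))
    gr$transcript_biotype <- tx$transcript_biotype[i]
  if (!is.null(tx$gene_biotype)) gr$gene_biotype <- tx$gene_biotype[i]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read an evidence track from a BED file
#'
#' BED3/BED6, 0-based half-open on disk, converted to the package's
#' 1-based closed convention on import. Header (`track`, `browser`, `#`)
#' lines are skipped; strand is kept when a strand column is present and
#' left unstranded (`*`) otherwise.
#'
#' @param path Path to a BED file.
#' @param track_name Label for the evidence track (e.g. `"H3K4me3"`,
#'   `"RAMPAGE"`, `"WTTS"`).
#' @return A `GRanges` with the track name stored in
#'   `S4Vectors::metadata()$track_name`.
#' @export
read_peaks <- function(path, track_name) {
  stopifnot(nzchar(track_name))
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  body <- raw[!grepl("^(track|browser|#)", raw) & nzchar(trimws(raw))]
  if (!length(body)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$track_name <- track_name
    return(gr)
  }
  fields <- strsplit(body, "\t")
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(starts) || any(starts < 0))
    stop("invalid BED coordinates in ", path)
  # pad ragged records (mixed BED3/BED6) to a uniform column count
  ncols <- lengths(fields)
  if (length(unique(ncols)) > 1L) {
    target <- min(max(ncols), 6L)
    defaults <- c(".", "0", ".")   # name, score, strand
    fields <- lapply(fields, function(f) {
      while (length(f) < target) f <- c(f, defaults[length(f) - 2L])
      f
    })
  }
  body <- vapply(fields, paste, "", collapse = "\t")
  tmp <- tempfile(fileext = ".bed")
  on.exit(unlink(tmp))
  writeLines(body, tmp)
  gr <- rtracklayer::import(tmp, format = "bed")
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::metadata(gr)$track_name <- track_name
  gr
}

#' Write an evidence track to BED
#' @param peaks A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "bed")
  invisible(path)
}

#' Read / write a genome FASTA
#' @param path FASTA path.
#' @return Named `DNAStringSet`.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome
#' @param genome Named `DNAStringSet`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read / write plain TSV tables with a header row
#' @param path TSV path.
#' @return A data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param x A data frame.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
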