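STOP_CODONS <- c("TAA", "TAG", "TGA")
ALT_START_CODONS <- c("ATG", "CTG", "GTG", "TTG")

#' Find open reading frames in a spliced transcript sequence
#'
#' Scans the three sense frames of a mature (sense-strand) transcript
#' sequence for maximal ORFs: for each stop codon, the ORF starting at the
#' earliest start codon downstream of the previous in-frame stop. A
#' trailing ORF with a start codon but no stop before the sequence end is
#' retained (the nonstop-decay precursor case). Start codons are `ATG`
#' alone or the vertebrate alternative-initiation set
#' `{ATG, CTG, GTG, TTG}`.
#'
#' @param seq Sense-strand nucleotide sequence (character or `DNAString`).
#' @param transcript_id Id recorded on each ORF row.
#' @param allow_alternative_starts Use the alternative start-codon set
#'   (default `TRUE`, matching ORF prediction with alternative initiation
#'   codons).
#' @return Data frame sorted longest-first with columns `transcript_id`,
#'   `orf_id`, `start` (1-based offset of the start codon in the spliced
#'   sequence), `stop_end` (1-based offset of the last base of the stop
#'   codon; `NA` when no stop), `has_stop`, `length_aa` (codons before the
#'   stop, including the initiator), `start_codon`, `frame` (0..2).
#' @export
find_orfs <- function(seq, transcript_id = "tx",
                      allow_alternative_starts = TRUE) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  if (L == 0L) stop("empty sequence")
  starts_set <- if (allow_alternative_starts) ALT_START_CODONS else "ATG"
  rows <- list()
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < 1L) next
    pos <- f + 1L + 3L * (seq_len(n_cod) - 1L)   # codon start offsets
    cod <- substring(s, pos, pos + 2L)
    is_start <- cod %in% starts_set
    is_stop <- cod %in% STOP_CODONS
    prev_stop <- 0L   # codon index of last stop seen
    stop_idx <- which(is_stop)
    seg_bounds <- c(0L, stop_idx)   # ORF search segments end at each stop
    for (k in seq_along(stop_idx)) {
      lo <- seg_bounds[k] + 1L; hi <- stop_idx[k] - 1L
      if (hi < lo) next
      cand <- which(is_start[lo:hi])
      if (!length(cand)) next
      i0 <- lo + cand[1L] - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = transcript_id,
        start = pos[i0],
        stop_end = pos[stop_idx[k]] + 2L,
        has_stop = TRUE,
        length_aa = stop_idx[k] - i0,
        start_codon = cod[i0], frame = f, stringsAsFactors = FALSE)
    }
    # trailing segment: start but no stop before sequence end
    lo <- if (length(stop_idx)) stop_idx[length(stop_idx)] + 1L else 1L
    if (lo <= n_cod) {
      cand <- which(is_start[lo:n_cod])
      if (length(cand)) {
        i0 <- lo + cand[1L] - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = transcript_id,
          start = pos[i0],
          stop_end = NA_integer_,
          has_stop = FALSE,
          length_aa = n_cod - i0 + 1L,
          start_codon = cod[i0], frame = f, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(0), orf_id = character(0),
                      start = integer(0), stop_end = integer(0),
                      has_stop = logical(0), length_aa = integer(0),
                      start_codon = character(0), frame = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[out$length_aa >= 1L, , drop = FALSE]
  out <- out[order(-out$length_aa, out$start), , drop = FALSE]
  out$orf_id <- paste0(out$transcript_id, ":", out$start)
  rownames(out) <- NULL
  out[, c("transcript_id", "orf_id", "start", "stop_end", "has_stop",
          "length_aa", "start_codon", "frame")]
}

#' Select the representative ORF of a transcript
#'
#' The three longest ORFs are eligible for protein homology support
#' (E-value at most `evalue_max`, coverage at least `min_cov` percent,
#' identity at least `min_ident` percent). The eligible ORF whose best
#' passing hit has the lowest E-value is the representative; when no hit
#' passes, the longest ORF is used.
#'
#' @param orfs ORF table from [find_orfs()] (longest-first).
#' @param homology Data frame with columns `query_id`, `subject_id`,
#'   `evalue`, `coverage_pct`, `identity_pct`, `search_kind`; queries are
#'   ORF ids. May be `NULL` or empty.
#' @param evalue_max,min_cov,min_ident Hit-acceptance thresholds.
#' @return One-row ORF data frame, or `NULL` when `orfs` is empty.
#' @export
select_representative_orf <- function(orfs, homology = NULL,
                                      evalue_max = 1e-6, min_cov = 60,
                                      min_ident = 95) {
  if (is.null(orfs) || nrow(orfs) == 0L) return(NULL)
  top <- orfs[seq_len(min(3L, nrow(orfs))), , drop = FALSE]
  if (!is.null(homology) && nrow(homology)) {
    h <- homology[homology$search_kind == "protein" &
                    homology$query_id %in% top$orf_id &
                    homology$evalue <= evalue_max &
                    homology$coverage_pct >= min_cov &
                    homology$identity_pct >= min_ident, , drop = FALSE]
    if (nrow(h)) {
      best_e <- tapply(h$evalue, h$query_id, min)
      win <- names(best_e)[which.min(best_e)]
      return(top[match(win, top$orf_id), , drop = FALSE])
    }
  }
  orfs[1L, , drop = FALSE]
}
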