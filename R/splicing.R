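# Per-transcript structure used by the event scanners: exon matrix,
# intron matrix, and intron keys ("start-end").
.tx_struct <- function(ts, id) {
  ex <- tx_exons(ts, id)
  em <- cbind(start = BiocGenerics::start(ex), end = BiocGenerics::end(ex))
  im <- tx_junctions(ts, id)
  list(id = id, exons = em, introns = im,
       ikey = if (nrow(im)) paste(im[, 1L], im[, 2L], sep = "-")
       else character(0))
}

.ev <- function(type, coords, tx_pair) {
  data.frame(event_type = type,
             coordinates = paste(coords, collapse = ":"),
             transcripts = paste(sort(tx_pair), collapse = ","),
             stringsAsFactors = FALSE)
}

# events where transcript `a` has an extra/changed structure vs `b`
.scan_pair <- function(a, b, strand) {
  out <- list()
  na <- nrow(a$exons)
  # SE: internal exon of a, b joins a's flanking exons directly
  if (na >= 3L && nrow(b$introns)) {
    for (k in 2:(na - 1L)) {
      u <- c(a$exons[k - 1L, 2L] + 1L, a$exons[k, 1L] - 1L)
      d <- c(a$exons[k, 2L] + 1L, a$exons[k + 1L, 1L] - 1L)
      if (paste(u[1L], d[2L], sep = "-") %in% b$ikey)
        out[[length(out) + 1L]] <-
          .ev("SE", c(u[1L], a$exons[k, 1L], a$exons[k, 2L], d[2L]),
              c(a$id, b$id))
    }
  }
  # RI: a splices an intron that b retains inside one exon with matched
  # outer boundaries
  if (nrow(a$introns)) {
    for (k in seq_len(nrow(a$introns))) {
      s1 <- a$exons[k, 1L]; e1 <- a$exons[k, 2L]
      s2 <- a$exons[k + 1L, 1L]; e2 <- a$exons[k + 1L, 2L]
      hit <- b$exons[, 1L] == s1 & b$exons[, 2L] == e2
      if (any(hit))
        out[[length(out) + 1L]] <-
          .ev("RI", c(s1, e1, s2, e2), c(a$id, b$id))
    }
  }
  # A5/A3: introns sharing exactly one boundary, where the exons
  # flanking the variable boundary overlap (a genuine local splice-site
  # shift, not a skipped-exon side effect)
  if (nrow(a$introns) && nrow(b$introns)) {
    overlap2 <- function(x, y) x[1L] <= y[2L] && y[1L] <= x[2L]
    for (i in seq_len(nrow(a$introns))) for (j in seq_len(nrow(b$introns))) {
      ai <- a$introns[i, ]; bj <- b$introns[j, ]
      if (ai[1L] == bj[1L] && ai[2L] != bj[2L]) {
        if (!overlap2(a$exons[i + 1L, ], b$exons[j + 1L, ])) next
        type <- if (strand == "+") "A3" else "A5"
        out[[length(out) + 1L]] <-
          .ev(type, c(ai[1L], sort(c(ai[2L], bj[2L]))), c(a$id, b$id))
      } else if (ai[2L] == bj[2L] && ai[1L] != bj[1L]) {
        if (!overlap2(a$exons[i, ], b$exons[j, ])) next
        type <- if (strand == "+") "A5" else "A3"
        out[[length(out) + 1L]] <-
          .ev(type, c(sort(c(ai[1L], bj[1L])), ai[2L]), c(a$id, b$id))
      }
    }
  }
  # MX: internal exons with shared outer flanking boundaries, mutually
  # absent and non-overlapping
  nb <- nrow(b$exons)
  if (na >= 3L && nb >= 3L) {
    for (k in 2:(na - 1L)) for (l in 2:(nb - 1L)) {
      ea <- a$exons[k, ]; eb <- b$exons[l, ]
      if (a$exons[k - 1L, 2L] != b$exons[l - 1L, 2L]) next
      if (a$exons[k + 1L, 1L] != b$exons[l + 1L, 1L]) next
      if (ea[1L] <= eb[2L] && eb[1L] <= ea[2L]) next  # overlap
      in_b <- any(b$exons[, 1L] == ea[1L] & b$exons[, 2L] == ea[2L])
      in_a <- any(a$exons[, 1L] == eb[1L] & a$exons[, 2L] == eb[2L])
      if (in_b || in_a) next
      pair <- if (ea[1L] < eb[1L]) c(ea, eb) else c(eb, ea)
      out[[length(out) + 1L]] <-
        .ev("MX", c(a$exons[k - 1L, 2L] + 1L, pair,
                    a$exons[k + 1L, 1L] - 1L), c(a$id, b$id))
    }
  }
  out
}

# AF/AL: distinct non-overlapping terminal exons joined to a common
# splice site; computed once per pair (symmetric)
.scan_terminal <- function(a, b, strand) {
  out <- list()
  if (!nrow(a$introns) || !nrow(b$introns)) return(out)
  na <- nrow(a$exons); nb <- nrow(b$exons)
  term <- function(first_genomic) {
    ea <- if (first_genomic) a$exons[1L, ] else a$exons[na, ]
    eb <- if (first_genomic) b$exons[1L, ] else b$exons[nb, ]
    ia <- if (first_genomic) a$introns[1L, ] else a$introns[nrow(a$introns), ]
    ib <- if (first_genomic) b$introns[1L, ] else b$introns[nrow(b$introns), ]
    shared <- if (first_genomic) ia[2L] == ib[2L] else ia[1L] == ib[1L]
    distinct <- !(ea[1L] == eb[1L] && ea[2L] == eb[2L]) &&
      (if (first_genomic) ea[2L] != eb[2L] else ea[1L] != eb[1L])
    overlap <- ea[1L] <= eb[2L] && eb[1L] <= ea[2L]
    if (shared && distinct && !overlap) {
      type <- if (first_genomic) {
        if (strand == "+") "AF" else "AL"
      } else {
        if (strand == "+") "AL" else "AF"
      }
      anchor <- if (first_genomic) ia[2L] else ia[1L]
      pair <- if (ea[1L] < eb[1L]) c(ea, eb) else c(eb, ea)
      return(.ev(type, c(pair, anchor), c(a$id, b$id)))
    }
    NULL
  }
  for (fg in c(TRUE, FALSE)) {
    e <- term(fg)
    if (!is.null(e)) out[[length(out) + 1L]] <- e
  }
  out
}

#' Enumerate local alternative-splicing events in a gene
#'
#' Pairwise comparison of a gene's transcripts yields skipped exons (SE),
#' retained introns (RI), alternative 5' and 3' splice sites (A5/A3,
#' strand-aware), mutually exclusive exons (MX), and alternative
#' first/last exons (AF/AL). Events are deduplicated by type and
#' defining coordinates; a coordinate-identical event supported by
#' several transcript pairs counts once, with all supporting transcripts
#' recorded.
#'
#' @param ts A `tx_set`.
#' @param gene_id Gene to scan.
#' @param include_use Also run [detect_use()] (default `TRUE`).
#' @return Data frame: `gene_id`, `event_type`, `coordinates`,
#'   `transcripts`. Empty for single-transcript genes.
#' @export
enumerate_events <- function(ts, gene_id, include_use = TRUE) {
  tids <- sort(ts$tx$transcript_id[ts$tx$gene_id == gene_id])
  empty <- data.frame(gene_id = character(0), event_type = character(0),
                      coordinates = character(0),
                      transcripts = character(0))
  if (length(tids) < 2L) return(empty)
  strand <- ts$tx[tids[1L], "strand"]
  st <- lapply(tids, function(id) .tx_struct(ts, id))
  evs <- list()
  for (i in seq_along(st)) for (j in seq_along(st)) {
    if (i == j) next
    evs <- c(evs, .scan_pair(st[[i]], st[[j]], strand))
    if (j > i) evs <- c(evs, .scan_terminal(st[[i]], st[[j]], strand))
  }
  if (include_use) {
    u <- detect_use(ts, gene_id)
    if (nrow(u))
      evs <- c(evs, lapply(seq_len(nrow(u)), function(r)
        u[r, c("event_type", "coordinates", "transcripts")]))
  }
  if (!length(evs)) return(empty)
  d <- do.call(rbind, evs)
  key <- paste(d$event_type, d$coordinates)
  tx_by_key <- tapply(d$transcripts, key, function(x)
    paste(sort(unique(unlist(strsplit(x, ",")))), collapse = ","))
  d <- d[!duplicated(key), , drop = FALSE]
  d$transcripts <- unname(tx_by_key[paste(d$event_type, d$coordinates)])
  d <- cbind(gene_id = gene_id, d, stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d[order(d$event_type, d$coordinates), , drop = FALSE]
}

#' Detect unique splice site exons (USE)
#'
#' A USE is a pair of internal exons from two transcripts of one gene
#' that overlap by at least one nucleotide while sharing no splice
#' junction: neither flanking intron of one exon occurs anywhere in the
#' other transcript's intron chain. Transcript termini are not splice
#' junctions, so only internal exons qualify.
#'
#' @param ts A `tx_set`.
#' @param gene_id Gene to scan.
#' @return Data frame: `gene_id`, `event_type` (`"USE"`),
#'   `coordinates`, `transcripts`.
#' @export
detect_use <- function(ts, gene_id) {
  tids <- sort(ts$tx$transcript_id[ts$tx$gene_id == gene_id])
  empty <- data.frame(gene_id = character(0), event_type = character(0),
                      coordinates = character(0),
                      transcripts = character(0))
  if (length(tids) < 2L) return(empty)
  st <- lapply(tids, function(id) .tx_struct(ts, id))
  out <- list()
  for (i in seq_along(st)) for (j in seq_along(st)) {
    if (j <= i) next
    a <- st[[i]]; b <- st[[j]]
    na <- nrow(a$exons); nb <- nrow(b$exons)
    if (na < 3L || nb < 3L) next
    for (k in 2:(na - 1L)) for (l in 2:(nb - 1L)) {
      ea <- a$exons[k, ]; eb <- b$exons[l, ]
      if (!(ea[1L] <= eb[2L] && eb[1L] <= ea[2L])) next
      fa <- c(paste(a$exons[k - 1L, 2L] + 1L, ea[1L] - 1L, sep = "-"),
              paste(ea[2L] + 1L, a$exons[k + 1L, 1L] - 1L, sep = "-"))
      fb <- c(paste(b$exons[l - 1L, 2L] + 1L, eb[1L] - 1L, sep = "-"),
              paste(eb[2L] + 1L, b$exons[l + 1L, 1L] - 1L, sep = "-"))
      if (any(fa %in% b$ikey) || any(fb %in% a$ikey)) next
      pair <- if (ea[1L] < eb[1L] || (ea[1L] == eb[1L] && ea[2L] < eb[2L]))
        c(ea, eb) else c(eb, ea)
      out[[length(out) + 1L]] <- .ev("USE", pair, c(a$id, b$id))
    }
  }
  if (!length(out)) return(empty)
  d <- do.call(rbind, out)
  key <- paste(d$event_type, d$coordinates)
  tx_by_key <- tapply(d$transcripts, key, function(x)
    paste(sort(unique(unlist(strsplit(x, ",")))), collapse = ","))
  d <- d[!duplicated(key), , drop = FALSE]
  d$transcripts <- unname(tx_by_key[paste(d$event_type, d$coordinates)])
  d <- cbind(gene_id = gene_id, d, stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d
}

#' Enumerate events for every gene in a set
#' @param ts A `tx_set`.
#' @param include_use Also detect USEs.
#' @return Row-bound event table over all genes.
#' @export
enumerate_all_events <- function(ts, include_use = TRUE) {
  parts <- lapply(unique(ts$tx$gene_id), function(g)
    enumerate_events(ts, g, include_use = include_use))
  do.call(rbind, parts)
}

#' Alternative-splicing summary per transcript, gene and tissue
#'
#' @param events Event table from [enumerate_all_events()].
#' @param ts A `tx_set`.
#' @param expressed Optional logical matrix (transcripts x tissues); when
#'   given, the per-tissue fraction of expressed transcripts involved in
#'   at least one event is reported.
#' @return List with `transcripts` (`transcript_id`, `in_as_event`),
#'   `genes` (`gene_id`, `n_events`), and `tissues` (`tissue`,
#'   `frac_expressed_tx_in_as`) or `NULL`.
#' @export
summarize_as <- function(events, ts, expressed = NULL) {
  involved <- unique(unlist(strsplit(events$transcripts, ",")))
  tx <- data.frame(transcript_id = ts$tx$transcript_id,
                   in_as_event = ts$tx$transcript_id %in% involved,
                   stringsAsFactors = FALSE)
  n_by_gene <- table(events$gene_id)
  genes <- data.frame(gene_id = unique(ts$tx$gene_id),
                      stringsAsFactors = FALSE)
  genes$n_events <- as.integer(n_by_gene[genes$gene_id])
  genes$n_events[is.na(genes$n_events)] <- 0L
  tissues <- NULL
  if (!is.null(expressed)) {
    frac <- vapply(colnames(expressed), function(tis) {
      e <- rownames(expressed)[expressed[, tis]]
      if (!length(e)) return(NA_real_)
      mean(e %in% involved)
    }, 0)
    tissues <- data.frame(tissue = colnames(expressed),
                          frac_expressed_tx_in_as = unname(frac),
                          stringsAsFactors = FALSE)
  }
  list(transcripts = tx, genes = genes, tissues = tissues)
}
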