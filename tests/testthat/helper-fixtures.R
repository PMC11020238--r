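# Hand-built transcript fixtures and independent oracles used across the
# suite. Coordinates are 1-based closed throughout.

mk_exons <- function(tid, gid, chrom, strand, coords) {
  m <- do.call(rbind, coords)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(m[, 1], m[, 2]),
                         strand = strand, transcript_id = tid,
                         gene_id = gid)
}

# ts from a list of transcripts: list(id =, gene =, chrom =, strand =,
# exons = list(c(s, e), ...))
mk_ts <- function(specs, ...) {
  grs <- lapply(specs, function(s)
    mk_exons(s$id, if (is.null(s$gene)) s$id else s$gene,
             if (is.null(s$chrom)) "chr1" else s$chrom,
             s$strand, s$exons))
  tx_set(suppressWarnings(do.call(c, grs)), ...)
}

mk_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

peaks_gr <- function(coords, chrom = "chr1", strand = "*") {
  if (!length(coords)) return(GenomicRanges::GRanges())
  m <- do.call(rbind, coords)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(m[, 1], m[, 2]),
                         strand = strand)
}

# --- independent oracles ----------------------------------------------

# hypergeometric upper tail by explicit binomial-coefficient summation
brute_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# transitive closure over all-pairs equivalence: an independent inline
# restatement of the fuzzy-equivalence rule plus component merging by
# label propagation (no union-find, no candidate bucketing)
brute_closure <- function(ts, params = equivalence_params()) {
  ids <- sort(ts$tx$transcript_id)
  n <- length(ids)
  tx <- ts$tx[ids, ]
  jx <- lapply(ids, function(id) tx_junctions(ts, id))
  end_ok <- function(pa, pb, sa, sb, span) {
    if (sa && sb) abs(pa - pb) <= span
    else abs(pa - pb) <= params$border_fuzz
  }
  eq <- function(i, j) {
    if (tx$chrom[i] != tx$chrom[j] || tx$strand[i] != tx$strand[j])
      return(FALSE)
    a <- jx[[i]]; b <- jx[[j]]
    if (nrow(a) != nrow(b)) return(FALSE)
    if (nrow(a) && max(abs(a - b)) > params$junction_fuzz) return(FALSE)
    end_ok(tx$tss[i], tx$tss[j], tx$tss_supported[i],
           tx$tss_supported[j], params$tss_window_span) &&
      end_ok(tx$tts[i], tx$tts[j], tx$tts_supported[i],
             tx$tts_supported[j], params$tts_window_span)
  }
  comp <- seq_len(n)
  if (n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (comp[i] != comp[j] && eq(i, j))
        comp[comp == comp[j]] <- comp[i]
  groups <- lapply(unname(split(ids, comp)), sort)
  groups[order(vapply(groups, `[`, "", 1))]
}

# exhaustive per-pair alternative-splicing scan, written independently
# from the package scanners: returns a sorted character set of
# "type coords" keys for one gene
brute_as_events <- function(ts, gene_id) {
  tids <- sort(ts$tx$transcript_id[ts$tx$gene_id == gene_id])
  if (length(tids) < 2) return(character(0))
  strand <- ts$tx[tids[1], "strand"]
  ex <- lapply(tids, function(id) {
    e <- tx_exons(ts, id)
    cbind(BiocGenerics::start(e), BiocGenerics::end(e))
  })
  names(ex) <- tids
  jset <- lapply(ex, function(m) {
    if (nrow(m) < 2) return(character(0))
    paste(m[-nrow(m), 2] + 1, m[-1, 1] - 1)
  })
  out <- character(0)
  add <- function(type, ...) {
    out <<- c(out, paste(type, paste(c(...), collapse = ":")))
  }
  for (a in tids) for (b in tids) {
    if (a == b) next
    ea <- ex[[a]]; eb <- ex[[b]]
    ja <- jset[[a]]; jb <- jset[[b]]
    na <- nrow(ea)
    # SE
    if (na >= 3) for (k in 2:(na - 1)) {
      u <- ea[k - 1, 2] + 1; d <- ea[k + 1, 1] - 1
      if (paste(u, d) %in% jb)
        add("SE", u, ea[k, 1], ea[k, 2], d)
    }
    # RI
    if (na >= 2) for (k in 1:(na - 1)) {
      if (any(eb[, 1] == ea[k, 1] & eb[, 2] == ea[k + 1, 2]))
        add("RI", ea[k, 1], ea[k, 2], ea[k + 1, 1], ea[k + 1, 2])
    }
    # A5/A3: variable-side flanking exons must overlap
    for (ii in seq_along(ja)) for (jj in seq_along(jb)) {
      pa <- as.integer(strsplit(ja[ii], " ")[[1]])
      pb <- as.integer(strsplit(jb[jj], " ")[[1]])
      if (pa[1] == pb[1] && pa[2] != pb[2] &&
          ea[ii + 1, 1] <= eb[jj + 1, 2] && eb[jj + 1, 1] <= ea[ii + 1, 2])
        add(if (strand == "+") "A3" else "A5",
            pa[1], min(pa[2], pb[2]), max(pa[2], pb[2]))
      if (pa[2] == pb[2] && pa[1] != pb[1] &&
          ea[ii, 1] <= eb[jj, 2] && eb[jj, 1] <= ea[ii, 2])
        add(if (strand == "+") "A5" else "A3",
            min(pa[1], pb[1]), max(pa[1], pb[1]), pa[2])
    }
    # MX
    nb <- nrow(eb)
    if (na >= 3 && nb >= 3) for (k in 2:(na - 1)) for (l in 2:(nb - 1)) {
      if (ea[k - 1, 2] == eb[l - 1, 2] && ea[k + 1, 1] == eb[l + 1, 1] &&
          (ea[k, 2] < eb[l, 1] || eb[l, 2] < ea[k, 1]) &&
          !any(eb[, 1] == ea[k, 1] & eb[, 2] == ea[k, 2]) &&
          !any(ea[, 1] == eb[l, 1] & ea[, 2] == eb[l, 2])) {
        p <- rbind(ea[k, ], eb[l, ])
        p <- p[order(p[, 1]), ]
        add("MX", ea[k - 1, 2] + 1, p[1, 1], p[1, 2], p[2, 1], p[2, 2],
            ea[k + 1, 1] - 1)
      }
    }
    # AF/AL (once per unordered pair)
    if (a < b && length(ja) && length(jb)) {
      f_a <- ea[1, ]; f_b <- eb[1, ]
      j_a <- as.integer(strsplit(ja[1], " ")[[1]])
      j_b <- as.integer(strsplit(jb[1], " ")[[1]])
      if (j_a[2] == j_b[2] && f_a[2] != f_b[2] &&
          (f_a[2] < f_b[1] || f_b[2] < f_a[1])) {
        p <- rbind(f_a, f_b); p <- p[order(p[, 1]), ]
        add(if (strand == "+") "AF" else "AL",
            p[1, 1], p[1, 2], p[2, 1], p[2, 2], j_a[2])
      }
      l_a <- ea[na, ]; l_b <- eb[nb, ]
      k_a <- as.integer(strsplit(ja[length(ja)], " ")[[1]])
      k_b <- as.integer(strsplit(jb[length(jb)], " ")[[1]])
      if (k_a[1] == k_b[1] && l_a[1] != l_b[1] &&
          (l_a[2] < l_b[1] || l_b[2] < l_a[1])) {
        p <- rbind(l_a, l_b); p <- p[order(p[, 1]), ]
        add(if (strand == "+") "AL" else "AF",
            p[1, 1], p[1, 2], p[2, 1], p[2, 2], k_a[1])
      }
    }
    # USE
    if (a < b && na >= 3 && nb >= 3)
      for (k in 2:(na - 1)) for (l in 2:(nb - 1)) {
        if (ea[k, 1] > eb[l, 2] || eb[l, 1] > ea[k, 2]) next
        fk <- c(paste(ea[k - 1, 2] + 1, ea[k, 1] - 1),
                paste(ea[k, 2] + 1, ea[k + 1, 1] - 1))
        fl <- c(paste(eb[l - 1, 2] + 1, eb[l, 1] - 1),
                paste(eb[l, 2] + 1, eb[l + 1, 1] - 1))
        if (any(fk %in% jb) || any(fl %in% ja)) next
        p <- rbind(ea[k, ], eb[l, ])
        p <- p[order(p[, 1], p[, 2]), ]
        add("USE", p[1, 1], p[1, 2], p[2, 1], p[2, 2])
      }
  }
  sort(unique(out))
}

event_keys <- function(events) {
  sort(unique(paste(events$event_type, events$coordinates)))
}

# random spliced genes over a shared exon grid (for exhaustive AS checks)
random_grid_gene <- function(n_tx, gene = "G", strand = "+") {
  grid <- cbind(seq(100, by = 400, length.out = 6),
                seq(100, by = 400, length.out = 6) + 199)
  specs <- list()
  for (i in seq_len(n_tx)) {
    pick <- sort(sample(6, sample(2:5, 1)))
    m <- grid[pick, , drop = FALSE]
    # occasionally shift a boundary to create A5/A3/USE variation
    # (shifts of 60 keep all introns positive on the 200-nt grid gaps)
    if (stats::runif(1) < 0.5) {
      r <- sample(nrow(m), 1)
      side <- sample(2, 1)
      m[r, side] <- m[r, side] + sample(c(-60, 60), 1)
    }
    specs[[i]] <- list(id = sprintf("%s_t%d", gene, i), gene = gene,
                       strand = strand,
                       exons = lapply(seq_len(nrow(m)),
                                      function(r) c(m[r, 1], m[r, 2])))
  }
  mk_ts(specs)
}

# flip a tx_set to the opposite strand in place: donors become acceptors
# and first exons become last exons
mirror_ts <- function(ts) {
  ex <- ts$exons
  str <- ifelse(as.character(BiocGenerics::strand(ex)) == "+", "-", "+")
  tx_set(GenomicRanges::GRanges(GenomeInfoDb::seqnames(ex),
                                IRanges::ranges(ex), strand = str,
                                transcript_id = ex$transcript_id,
                                gene_id = ex$gene_id))
}
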