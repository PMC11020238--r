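#' Simulation configuration
#'
#' Defaults define the emulated study conditions: a multi-tissue
#' transcript catalogue roughly half protein-coding, with NMD transcripts
#' and lncRNAs as the dominant noncoding classes, a fifth of features
#' tissue-specific, log-normal expression noise, duplicate transcript
#' structures re-assembled across tissues with border jitter inside the
#' 100-nt collapse fuzz, and a trait-QTL table with one planted similar
#' trait pair sharing 80% of its QTL-associated genes.
#'
#' @param n_genes Number of genes (default 60).
#' @param n_tissues Number of tissues (default 10).
#' @param biotype_fracs Named fractions over planted transcript classes;
#'   must sum to 1.
#' @param n_polya_artifacts Unspliced genomic poly(A)-primed artifacts
#'   appended to the catalogue (default 4).
#' @param frac_tissue_specific,frac_housekeeping Expression-profile
#'   fractions; the remainder is broadly expressed.
#' @param noise_sigma Log-normal sigma on RPKM (default 0.25).
#' @param dup_frac Fraction of eligible genes whose template transcript
#'   is re-emitted from other tissues as a structural duplicate group
#'   (default 0.5).
#' @param dup_copies Candidate duplicate counts per duplicated gene.
#' @param border_jitter Outward border shift of every duplicate copy in
#'   nt (default 40, inside the 100-nt fuzz; applied exactly, so
#'   threshold experiments are sharp).
#' @param junction_jitter Shift applied to every internal exon boundary
#'   of a duplicate copy (default 0; nonzero values corrupt planted
#'   coding sequence and are meant for structural experiments only).
#' @param frac_validated Fraction of transcripts with planted
#'   border-evidence support (default 0.7).
#' @param frac_promoter_evidence Fraction of single-exon genes with a
#'   planted promoter histone/ATAC peak (default 0.7).
#' @param n_extension_genes Coding genes whose reference copy is trimmed
#'   to plant a gene-border extension (default 6).
#' @param n_bifunctional Coding genes given a nested NMD isoform so the
#'   locus transcribes both coding and PAT transcripts (default 6; capped
#'   by the number of unused host genes).
#' @param n_traits,qtls_per_trait Trait-QTL table shape.
#' @param similar_pairs List of planted similar trait pairs.
#' @param similar_overlap Fraction of QTL-associated genes shared by a
#'   planted pair (default 0.8).
#' @param frac_qtl_inside Fraction of QTLs placed inside their target
#'   gene body (default 0.5).
#' @return Validated config list.
#' @export
sim_config <- function(n_genes = 60L, n_tissues = 10L,
                       biotype_fracs = c(protein_coding = 0.30,
                                         nmd = 0.12, nsd = 0.06,
                                         lncRNA_antisense = 0.10,
                                         lncRNA_sense_intronic = 0.06,
                                         lncRNA_intragenic = 0.06,
                                         lncRNA_intergenic = 0.14,
                                         sncRNA = 0.10,
                                         pseudogene = 0.06),
                       n_polya_artifacts = 4L,
                       frac_tissue_specific = 0.2,
                       frac_housekeeping = 0.2,
                       noise_sigma = 0.25,
                       dup_frac = 0.5, dup_copies = 2:3,
                       border_jitter = 40L, junction_jitter = 0L,
                       frac_validated = 0.7,
                       frac_promoter_evidence = 0.7,
                       n_extension_genes = 6L, n_bifunctional = 6L,
                       n_traits = 12L, qtls_per_trait = 8L,
                       similar_pairs = list(c("trait01", "trait02"),
                                            c("trait03", "trait04"),
                                            c("trait05", "trait06")),
                       similar_overlap = 0.8,
                       frac_qtl_inside = 0.5) {
  stopifnot(n_genes >= 1L, n_tissues >= 2L,
            abs(sum(biotype_fracs) - 1) < 1e-8,
            all(biotype_fracs >= 0),
            frac_tissue_specific + frac_housekeeping <= 1)
  counts <- diff(c(0L, round(cumsum(biotype_fracs) * n_genes)))
  names(counts) <- names(biotype_fracs)
  hosted <- sum(counts[c("lncRNA_antisense", "lncRNA_sense_intronic",
                         "lncRNA_intragenic")])
  if (3L * counts[["protein_coding"]] < hosted)
    stop("config infeasible: too few protein-coding host genes for the ",
         "hosted lncRNA classes")
  list(n_genes = n_genes, n_tissues = n_tissues,
       biotype_counts = counts, n_polya_artifacts = n_polya_artifacts,
       frac_tissue_specific = frac_tissue_specific,
       frac_housekeeping = frac_housekeeping, noise_sigma = noise_sigma,
       dup_frac = dup_frac, dup_copies = dup_copies,
       border_jitter = border_jitter, junction_jitter = junction_jitter,
       frac_validated = frac_validated,
       frac_promoter_evidence = frac_promoter_evidence,
       n_extension_genes = n_extension_genes,
       n_bifunctional = n_bifunctional, n_traits = n_traits,
       qtls_per_trait = qtls_per_trait, similar_pairs = similar_pairs,
       similar_overlap = similar_overlap,
       frac_qtl_inside = frac_qtl_inside,
       tissues = sprintf("tissue%02d", seq_len(n_tissues)))
}

# Random-sequence helpers. {A,C}-alphabet stretches contain no TG
# dinucleotide, so no start codon (ATG/CTG/GTG/TTG) can ever form in
# them; planting all functional sequence over {A,C} plus an explicit
# ATG...TAA makes the planted ORF the only ORF of the transcript.
# {A,G} genomic stretches are start- AND stop-codon free on BOTH strands
# (sense {A,G} has no T, antisense {C,T} has no A/G where needed), so
# guard flanks and planted introns use {A,G} regardless of which strand
# later transcribes them.
.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
.rand_ac <- function(n) paste(sample(c("A", "C"), n, replace = TRUE),
                              collapse = "")
.rand_ag <- function(n) paste(sample(c("A", "G"), n, replace = TRUE),
                              collapse = "")
.ac_codons <- function(n) .rand_ac(3L * n)

.seq_coding <- function(total_len, last_exon_w) {
  u5 <- 50L
  aa <- (total_len - u5 - 3L - 30L) %/% 3L
  stopifnot(aa >= 45L)
  stop_end <- u5 + 3L * aa + 3L
  u3 <- total_len - stop_end
  stopifnot(u3 < last_exon_w)   # stop must sit inside the final exon
  paste0(.rand_ac(u5), "ATG", .ac_codons(aa - 1L), "TAA", .rand_ac(u3))
}
.seq_nmd <- function(total_len, last_exon_w, stop_dist = 150L) {
  fj <- total_len - last_exon_w
  stop_end_target <- fj - stop_dist
  u5 <- 50L
  aa <- (stop_end_target - u5 - 3L) %/% 3L
  stopifnot(aa >= 45L)
  stop_end <- u5 + 3L * aa + 3L
  paste0(.rand_ac(u5), "ATG", .ac_codons(aa - 1L), "TAA",
         .rand_ac(total_len - stop_end))
}
.seq_nsd <- function(total_len) {
  u5 <- 50L
  n_cod <- (total_len - u5 - 3L) %/% 3L
  rest <- total_len - u5 - 3L - 3L * n_cod
  stopifnot(n_cod >= 45L)
  paste0(.rand_ac(u5), "ATG", .ac_codons(n_cod), .rand_ac(rest))
}

.revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# queue a sense-sequence write over exon slots of the genome buffer
.plant_tx <- function(writes, starts, ends, strand, s) {
  w <- ends - starts + 1L
  stopifnot(nchar(s) == sum(w))
  n <- length(w)
  if (strand == "+") {
    offs <- cumsum(c(0L, w[-n]))
    for (i in seq_len(n))
      writes[[length(writes) + 1L]] <-
        list(start = starts[i], seq = substr(s, offs[i] + 1L,
                                             offs[i] + w[i]))
  } else {
    wt <- rev(w)                       # widths in transcript order
    toffs <- cumsum(c(0L, wt[-n]))
    for (i in seq_len(n)) {
      j <- n - i + 1L                  # transcript piece for exon i
      piece <- substr(s, toffs[j] + 1L, toffs[j] + w[i])
      writes[[length(writes) + 1L]] <-
        list(start = starts[i], seq = .revcomp_chr(piece))
    }
  }
  writes
}

.apply_writes <- function(buf, writes) {
  for (w in writes) {
    chars <- strsplit(w$seq, "")[[1L]]
    buf[w$start:(w$start + length(chars) - 1L)] <- chars
  }
  buf
}

#' Simulate an annotated multi-tissue transcript catalogue
#'
#' Generates a genome, a transcript catalogue with planted biotypes,
#' structural duplicate groups, alternative isoforms, poly(A) artifacts,
#' a trimmed reference annotation planting gene-border extensions, and
#' the homology / coding-potential side tables -- all with ground truth.
#' Planted sequences satisfy exactly the classification rule of their
#' class and violate all others (the planted ORF is the only ORF of a
#' coding-class transcript; noncoding transcripts carry no start codon
#' at all). Deterministic given `seed`.
#'
#' @param config [sim_config()].
#' @param seed Integer seed.
#' @return List: `ts` (`tx_set`), `genome` (`DNAStringSet`), `reference`
#'   (`tx_set`), `truth` (list of `transcripts` and `genes` data
#'   frames), `homology`, `coding_potential` (named logical), `config`.
#' @export
simulate_annotation <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  chrom <- "chr1"
  GUARD <- 400L
  classes <- rep(names(config$biotype_counts), config$biotype_counts)
  standalone <- classes[!grepl("antisense|sense_intronic|intragenic",
                               classes)]
  hosted <- classes[grepl("antisense|sense_intronic|intragenic", classes)]

  ex_rows <- list(); tx_meta <- list(); truth_tx <- list()
  truth_gene <- list(); ref_rows <- list(); writes <- list()
  homology <- list(); coding_pot <- c()
  host_info <- list()   # per coding gene: exon coords for hosting
  cursor <- 600L
  gi <- 0L

  new_exons <- function(tid, gid, starts, ends, strand) {
    data.frame(chrom = chrom, start = starts, end = ends, strand = strand,
               transcript_id = tid, gene_id = gid,
               stringsAsFactors = FALSE)
  }

  ext_assigned <- 0L
  for (cls in standalone) {
    gi <- gi + 1L
    gid <- sprintf("G%03d", gi)
    tid <- sprintf("TX%03d", gi)
    strand <- sample(c("+", "-"), 1L)
    is_ext <- cls == "protein_coding" &&
      ext_assigned < config$n_extension_genes
    if (is_ext) ext_assigned <- ext_assigned + 1L

    if (cls %in% c("protein_coding", "nmd", "pseudogene")) {
      ew <- if (is_ext) c(550L, 260L, 240L, 550L)
      else c(sample(280:340, 1L), sample(220:280, 1L),
             sample(200:260, 1L), sample(180:240, 1L))
      iw <- sample(450:650, length(ew) - 1L, replace = TRUE)
    } else if (cls == "nsd") {
      ew <- c(sample(280:340, 1L), sample(220:280, 1L),
              sample(180:240, 1L))
      iw <- sample(400:600, length(ew) - 1L, replace = TRUE)
    } else if (cls == "lncRNA_intergenic") {
      n_ex <- sample(3:4, 1L)
      ew <- sample(160:260, n_ex, replace = TRUE)
      iw <- sample(320:480, n_ex - 1L, replace = TRUE)
    } else if (cls == "sncRNA") {
      ew <- sample(120:180, 1L); iw <- integer(0)
    }
    starts <- cursor + cumsum(c(0L, ew[-length(ew)] + iw))
    ends <- starts + ew - 1L
    span <- c(starts[1L], ends[length(ends)])
    total <- sum(ew)

    # 3'-terminal exon width in transcript orientation
    last_w <- if (strand == "+") ew[length(ew)] else ew[1L]
    s <- switch(cls,
      protein_coding = .seq_coding(total, last_w),
      nmd = .seq_nmd(total, last_w),
      pseudogene = .seq_nmd(total, last_w),
      nsd = .seq_nsd(total),
      .rand_ac(total))
    # guards: both-strand codon-free flanks so duplicate border
    # extensions can never create or destroy an ORF
    writes[[length(writes) + 1L]] <-
      list(start = span[1L] - GUARD, seq = .rand_ag(GUARD))
    writes[[length(writes) + 1L]] <-
      list(start = span[2L] + 1L, seq = .rand_ag(GUARD))
    # lncRNA introns planted codon-free so spliced-in intron content of
    # alternative isoforms cannot introduce a start codon
    if (cls == "lncRNA_intergenic" && length(iw))
      for (k in seq_along(iw))
        writes[[length(writes) + 1L]] <-
          list(start = ends[k] + 1L, seq = .rand_ag(iw[k]))
    writes <- .plant_tx(writes, starts, ends, strand, s)

    ex_rows[[tid]] <- new_exons(tid, gid, starts, ends, strand)
    v5 <- is_ext || stats::runif(1) < config$frac_validated
    v3 <- is_ext || stats::runif(1) < config$frac_validated
    tx_meta[[tid]] <- data.frame(
      transcript_id = tid, gene_id = gid,
      tissues = config$tissues[1L + (gi %% config$n_tissues)],
      v5 = v5, v3 = v3, stringsAsFactors = FALSE)
    tbio <- if (cls == "pseudogene") "nmd" else cls
    truth_tx[[tid]] <- data.frame(
      transcript_id = tid, gene_id = gid, biotype = tbio,
      duplicate_group = tid, is_template = TRUE, polya_artifact = FALSE,
      validated5 = v5, validated3 = v3, stringsAsFactors = FALSE)
    gbio <- switch(cls, protein_coding = "protein_coding",
                   pseudogene = "pseudogene", "noncoding")
    ext5 <- 0L; ext3 <- 0L; kind <- ""
    if (is_ext) {
      which_ext <- c("five_prime", "three_prime", "both")[
        1L + (ext_assigned %% 3L)]
      if (which_ext %in% c("five_prime", "both"))
        ext5 <- sample(120:350, 1L)
      if (which_ext %in% c("three_prime", "both"))
        ext3 <- sample(120:350, 1L)
      kind <- which_ext
    }
    truth_gene[[gid]] <- data.frame(
      gene_id = gid, biotype = gbio, class = cls,
      single_exon = length(ew) == 1L,
      promoter_evidence = length(ew) == 1L &&
        stats::runif(1) < config$frac_promoter_evidence,
      ext5_nt = ext5, ext3_nt = ext3, ext_kind = kind,
      ref_trim5 = ext5, ref_trim3 = ext3,
      host_gene = "", stringsAsFactors = FALSE)
    if (cls == "pseudogene")
      homology[[length(homology) + 1L]] <- data.frame(
        query_id = gid, subject_id = paste0("vert_", gid),
        evalue = 1e-40, coverage_pct = 95, identity_pct = 98,
        search_kind = "nucleotide", stringsAsFactors = FALSE)
    if (cls %in% c("protein_coding", "nmd", "nsd", "pseudogene")) {
      coding_pot[tid] <- TRUE
      if (cls == "protein_coding" && stats::runif(1) < 0.5)
        homology[[length(homology) + 1L]] <- data.frame(
          query_id = paste0(tid, ":51"),
          subject_id = paste0("uniprot_", tid), evalue = 1e-20,
          coverage_pct = 80, identity_pct = 97,
          search_kind = "protein", stringsAsFactors = FALSE)
    } else coding_pot[tid] <- FALSE
    if (cls == "protein_coding")
      host_info[[gid]] <- list(tid = tid, starts = starts, ends = ends,
                               strand = strand, used_introns = integer(0),
                               tail_used = FALSE, is_ext = is_ext)
    # alternative isoforms on spliced intergenic lncRNA genes
    if (cls == "lncRNA_intergenic" && length(ew) >= 3L) {
      iso <- 0L
      # isoforms share the template's terminal exons, hence its border
      # evidence: they inherit the template's validation flags
      add_iso <- function(st, en, tag) {
        iso_id <- sprintf("%s_%s", tid, tag)
        ex_rows[[iso_id]] <<- new_exons(iso_id, gid, st, en, strand)
        tx_meta[[iso_id]] <<- data.frame(
          transcript_id = iso_id, gene_id = gid,
          tissues = config$tissues[1L + ((gi + 1L) %% config$n_tissues)],
          v5 = v5, v3 = v3, stringsAsFactors = FALSE)
        truth_tx[[iso_id]] <<- data.frame(
          transcript_id = iso_id, gene_id = gid,
          biotype = "lncRNA_intergenic", duplicate_group = iso_id,
          is_template = FALSE, polya_artifact = FALSE,
          validated5 = v5, validated3 = v3,
          stringsAsFactors = FALSE)
        coding_pot[iso_id] <<- FALSE
      }
      if (length(ew) >= 4L) {
        add_iso(starts[-2L], ends[-2L], "se")            # skipped exon
        sh <- 40L                                        # unique-site exon
        st2 <- starts; en2 <- ends
        st2[3L] <- st2[3L] + sh; en2[3L] <- en2[3L] + sh
        add_iso(st2, en2, "use")
      } else {
        add_iso(c(starts[1L], starts[3L]),               # retained intron
                c(ends[2L], ends[3L]), "ri")
      }
    }
    cursor <- span[2L] + GUARD + 2500L
  }

  # hosted lncRNAs inside / against protein-coding hosts
  host_ids <- names(host_info)
  hi <- 0L
  for (cls in hosted) {
    gi <- gi + 1L
    gid <- sprintf("G%03d", gi)
    tid <- sprintf("TX%03d", gi)
    # one hosted lncRNA per coding host, so no two hosted single-exon
    # genes can land inside each other's promoter window
    tries <- 0L
    repeat {
      hi <- hi + 1L
      tries <- tries + 1L
      if (tries > length(host_ids))
        stop("config infeasible: not enough unused host genes")
      hgid <- host_ids[1L + ((hi - 1L) %% length(host_ids))]
      h <- host_info[[hgid]]
      if (length(h$used_introns) || h$tail_used) next
      if (cls == "lncRNA_intragenic") {
        if (!h$is_ext) break
      } else break
    }
    if (cls == "lncRNA_intragenic") {
      host_info[[hgid]]$tail_used <- TRUE
      strand <- h$strand
      if (strand == "+") {
        st <- h$ends[length(h$ends)] - 20L
        en <- st + 279L
      } else {
        en <- h$starts[1L] + 20L
        st <- en - 279L
      }
      # overlapping stretch is the host's {A,C} 3' UTR; rewrite stays
      # in-alphabet, the extension runs into the host's {A,C} guard
      writes <- .plant_tx(writes, st, en, strand, .rand_ac(280L))
    } else {
      free <- setdiff(seq_len(length(h$starts) - 1L), h$used_introns)
      k <- free[1L]
      host_info[[hgid]]$used_introns <- c(h$used_introns, k)
      i_lo <- h$ends[k] + 1L; i_hi <- h$starts[k + 1L] - 1L
      wdt <- if (cls == "lncRNA_antisense") 260L else 230L
      st <- i_lo + 30L
      en <- st + wdt - 1L
      stopifnot(en <= i_hi - 30L)
      strand <- if (cls == "lncRNA_antisense") {
        if (h$strand == "+") "-" else "+"
      } else h$strand
      writes <- .plant_tx(writes, st, en, strand, .rand_ac(en - st + 1L))
    }
    ex_rows[[tid]] <- new_exons(tid, gid, st, en, strand)
    v5 <- stats::runif(1) < config$frac_validated
    v3 <- stats::runif(1) < config$frac_validated
    tx_meta[[tid]] <- data.frame(
      transcript_id = tid, gene_id = gid,
      tissues = config$tissues[1L + (gi %% config$n_tissues)],
      v5 = v5, v3 = v3, stringsAsFactors = FALSE)
    truth_tx[[tid]] <- data.frame(
      transcript_id = tid, gene_id = gid, biotype = cls,
      duplicate_group = tid, is_template = TRUE, polya_artifact = FALSE,
      validated5 = v5, validated3 = v3, stringsAsFactors = FALSE)
    truth_gene[[gid]] <- data.frame(
      gene_id = gid, biotype = "noncoding", class = cls,
      single_exon = TRUE,
      promoter_evidence = stats::runif(1) < config$frac_promoter_evidence,
      ext5_nt = 0L, ext3_nt = 0L, ext_kind = "",
      ref_trim5 = 0L, ref_trim3 = 0L, host_gene = hgid,
      stringsAsFactors = FALSE)
    coding_pot[tid] <- FALSE
  }

  # bifunctional loci: plant a spliced NMD isoform inside the first
  # intron of coding genes left unused by the hosted lncRNAs, so the
  # gene transcribes both a protein-coding and a PAT transcript without
  # changing its span or touching planted sequence
  bif_hosts <- Filter(function(g) {
    h <- host_info[[g]]
    k <- length(h$starts) - 1L
    k >= 1L && !(k %in% h$used_introns)
  }, names(host_info))
  bif_hosts <- utils::head(bif_hosts, config$n_bifunctional)
  for (hgid in bif_hosts) {
    h <- host_info[[hgid]]
    k <- length(h$starts) - 1L
    tid <- paste0(h$tid, "_pat")
    i_lo <- h$ends[k] + 1L; i_hi <- h$starts[k + 1L] - 1L
    strand <- h$strand
    # 210-nt first and 60-nt last exon in transcript orientation
    g1 <- if (strand == "+") 210L else 60L
    g2 <- if (strand == "+") 60L else 210L
    iw <- 40L
    stopifnot(i_lo + 20L + g1 + iw + g2 <= i_hi - 20L)
    st <- c(i_lo + 20L, i_lo + 20L + g1 + iw)
    en <- c(st[1L] + g1 - 1L, st[2L] + g2 - 1L)
    # ORF stop 62 spliced nt upstream of the final junction (> 50)
    aa <- 45L
    s <- paste0(.rand_ac(10L), "ATG", .ac_codons(aa - 1L), "TAA",
                .rand_ac(270L - 10L - 3L * aa - 3L))
    writes <- .plant_tx(writes, st, en, strand, s)
    ex_rows[[tid]] <- new_exons(tid, hgid, st, en, strand)
    v5b <- stats::runif(1) < config$frac_validated
    v3b <- stats::runif(1) < config$frac_validated
    tx_meta[[tid]] <- data.frame(
      transcript_id = tid, gene_id = hgid,
      tissues = config$tissues[1L + (length(tx_meta) %% config$n_tissues)],
      v5 = v5b, v3 = v3b, stringsAsFactors = FALSE)
    truth_tx[[tid]] <- data.frame(
      transcript_id = tid, gene_id = hgid, biotype = "nmd",
      duplicate_group = tid, is_template = FALSE,
      polya_artifact = FALSE, validated5 = v5b, validated3 = v3b,
      stringsAsFactors = FALSE)
    coding_pot[tid] <- TRUE
    host_info[[hgid]]$used_introns <- c(h$used_introns, k)
  }

  # genomic poly(A) artifacts: unspliced, A-run planted 3' of the TTS
  for (a in seq_len(config$n_polya_artifacts)) {
    gi <- gi + 1L
    gid <- sprintf("G%03d", gi)
    tid <- sprintf("TX%03d", gi)
    strand <- sample(c("+", "-"), 1L)
    wdt <- 300L
    st <- cursor; en <- st + wdt - 1L
    writes[[length(writes) + 1L]] <-
      list(start = st - GUARD, seq = .rand_ac(GUARD))
    writes <- .plant_tx(writes, st, en, strand, .rand_ac(wdt))
    if (strand == "+")
      writes[[length(writes) + 1L]] <-
        list(start = en + 1L, seq = strrep("A", 22L))
    else
      writes[[length(writes) + 1L]] <-
        list(start = st - 22L, seq = strrep("T", 22L))
    ex_rows[[tid]] <- new_exons(tid, gid, st, en, strand)
    tx_meta[[tid]] <- data.frame(
      transcript_id = tid, gene_id = gid,
      tissues = config$tissues[1L + (gi %% config$n_tissues)],
      v5 = FALSE, v3 = FALSE, stringsAsFactors = FALSE)
    truth_tx[[tid]] <- data.frame(
      transcript_id = tid, gene_id = gid, biotype = "lncRNA_intergenic",
      duplicate_group = tid, is_template = TRUE, polya_artifact = TRUE,
      validated5 = FALSE, validated3 = FALSE, stringsAsFactors = FALSE)
    truth_gene[[gid]] <- data.frame(
      gene_id = gid, biotype = "noncoding", class = "artifact",
      single_exon = TRUE, promoter_evidence = TRUE,
      ext5_nt = 0L, ext3_nt = 0L, ext_kind = "",
      ref_trim5 = 0L, ref_trim3 = 0L, host_gene = "",
      stringsAsFactors = FALSE)
    coding_pot[tid] <- FALSE
    cursor <- en + GUARD + 2500L
  }

  truth_tx <- do.call(rbind, truth_tx)
  truth_gene <- do.call(rbind, truth_gene)
  tx_meta <- do.call(rbind, tx_meta)

  # duplicate groups: re-emit templates from other tissues with exact
  # outward border extension (and optional junction shift)
  elig <- truth_gene$gene_id[truth_gene$class %in%
    c("protein_coding", "nmd", "nsd", "lncRNA_intergenic") &
    truth_gene$ext_kind == ""]
  n_dup <- round(config$dup_frac * length(elig))
  dup_genes <- if (n_dup) sort(sample(elig, n_dup)) else character(0)
  # duplicate copies widen the gene span by border_jitter at each end,
  # which is itself a planted both-end extension over the reference
  if (config$border_jitter > 0L && length(dup_genes)) {
    i <- match(dup_genes, truth_gene$gene_id)
    truth_gene$ext5_nt[i] <- config$border_jitter
    truth_gene$ext3_nt[i] <- config$border_jitter
    truth_gene$ext_kind[i] <- "both"
  }
  for (gidd in dup_genes) {
    templ <- truth_tx$transcript_id[truth_tx$gene_id == gidd &
                                      truth_tx$is_template][1L]
    e <- ex_rows[[templ]]
    n_cop <- sample(config$dup_copies, 1L)
    own_tis <- tx_meta$tissues[tx_meta$transcript_id == templ]
    other <- setdiff(config$tissues, own_tis)
    for (cc in seq_len(n_cop)) {
      cid <- sprintf("%s_d%d", templ, cc)
      ce <- e
      ne <- nrow(ce)
      if (config$junction_jitter > 0L && ne >= 2L) {
        j <- config$junction_jitter
        ce$end[-ne] <- ce$end[-ne] + j
        ce$start[-1L] <- ce$start[-1L] + j
      }
      bj <- config$border_jitter
      ce$start[1L] <- ce$start[1L] - bj
      ce$end[ne] <- ce$end[ne] + bj
      ce$transcript_id <- cid
      ex_rows[[cid]] <- ce
      tx_meta <- rbind(tx_meta, data.frame(
        transcript_id = cid, gene_id = gidd,
        tissues = other[1L + ((cc - 1L) %% length(other))],
        v5 = truth_tx$validated5[truth_tx$transcript_id == templ],
        v3 = truth_tx$validated3[truth_tx$transcript_id == templ],
        stringsAsFactors = FALSE))
      truth_tx <- rbind(truth_tx, data.frame(
        transcript_id = cid, gene_id = gidd,
        biotype = truth_tx$biotype[truth_tx$transcript_id == templ],
        duplicate_group = templ, is_template = FALSE,
        polya_artifact = FALSE,
        validated5 = truth_tx$validated5[truth_tx$transcript_id == templ],
        validated3 = truth_tx$validated3[truth_tx$transcript_id == templ],
        stringsAsFactors = FALSE))
      coding_pot[cid] <- coding_pot[[templ]]
    }
  }

  # genome assembly
  glen <- cursor + 3000L
  buf <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  buf <- .apply_writes(buf, writes)
  genome <- Biostrings::DNAStringSet(paste(buf, collapse = ""))
  names(genome) <- chrom

  exd <- do.call(rbind, ex_rows)
  exons <- GenomicRanges::GRanges(exd$chrom,
                                  IRanges::IRanges(exd$start, exd$end),
                                  strand = exd$strand,
                                  transcript_id = exd$transcript_id,
                                  gene_id = exd$gene_id)
  ts <- tx_set(exons,
               tissues = stats::setNames(tx_meta$tissues,
                                         tx_meta$transcript_id),
               tss_supported = stats::setNames(tx_meta$v5,
                                               tx_meta$transcript_id),
               tts_supported = stats::setNames(tx_meta$v3,
                                               tx_meta$transcript_id))

  # clean the poly(A) window of every non-artifact single-exon
  # transcript so the artifact detector has planted 100% specificity
  single <- ts$tx[ts$tx$n_exons == 1L, , drop = FALSE]
  art <- truth_tx$transcript_id[truth_tx$polya_artifact]
  gstr <- genome[[chrom]]
  for (k in seq_len(nrow(single))) {
    if (single$transcript_id[k] %in% art) next
    tts <- single$tts[k]
    rng <- if (single$strand[k] == "+") c(tts + 1L, tts + 30L)
    else c(tts - 30L, tts - 1L)
    win <- as.character(Biostrings::subseq(gstr, rng[1L], rng[2L]))
    if (single$strand[k] == "-") win <- .revcomp_chr(win)
    while (has_polya_run(win)) {
      win <- .rand_ac(30L)
    }
    w <- if (single$strand[k] == "-") .revcomp_chr(win) else win
    gstr <- Biostrings::replaceAt(
      gstr, IRanges::IRanges(rng[1L], rng[2L]), w)
  }
  genome <- Biostrings::DNAStringSet(gstr)
  names(genome) <- chrom

  # reference annotation: template copies, terminal exons trimmed by the
  # planted extension amounts
  for (gid in truth_gene$gene_id[truth_gene$class != "artifact"]) {
    templ <- truth_tx$transcript_id[truth_tx$gene_id == gid &
                                      truth_tx$is_template][1L]
    e <- ex_rows[[templ]]
    tg <- truth_gene[truth_gene$gene_id == gid, ]
    ne <- nrow(e)
    strand <- e$strand[1L]
    if (tg$ref_trim5 > 0L) {
      if (strand == "+") e$start[1L] <- e$start[1L] + tg$ref_trim5
      else e$end[ne] <- e$end[ne] - tg$ref_trim5
    }
    if (tg$ref_trim3 > 0L) {
      if (strand == "+") e$end[ne] <- e$end[ne] - tg$ref_trim3
      else e$start[1L] <- e$start[1L] + tg$ref_trim3
    }
    e$transcript_id <- paste0("REF.", templ)
    e$gene_id <- paste0("REFG.", gid)
    ref_rows[[gid]] <- e
  }
  refd <- do.call(rbind, ref_rows)
  ref_exons <- GenomicRanges::GRanges(
    refd$chrom, IRanges::IRanges(refd$start, refd$end),
    strand = refd$strand, transcript_id = refd$transcript_id,
    gene_id = refd$gene_id)
  reference <- tx_set(ref_exons, dataset = "ensembl_ref")

  homology <- if (length(homology)) do.call(rbind, homology)
  else data.frame(query_id = character(0), subject_id = character(0),
                  evalue = numeric(0), coverage_pct = numeric(0),
                  identity_pct = numeric(0), search_kind = character(0))
  rownames(truth_tx) <- NULL; rownames(truth_gene) <- NULL
  list(ts = ts, genome = genome, reference = reference,
       truth = list(transcripts = truth_tx, genes = truth_gene),
       homology = homology, coding_potential = coding_pot,
       config = config)
}

#' Simulate a per-tissue expression matrix with planted profiles
#'
#' Expression is planted per duplicate group (one underlying molecule):
#' tissue-specific groups get RPKM far above 1 in exactly one tissue and
#' far below 1 elsewhere, housekeepers a common level in every tissue,
#' broad groups an intermediate level in a random multi-tissue subset
#' covering all assembled tissues. Log-normal noise is applied and
#' clamped so the planted expressed/not-expressed calls survive.
#'
#' @param sim Output of [simulate_annotation()].
#' @param seed Integer seed.
#' @return List: `em` (an [expression_matrix()]), `truth_expression`
#'   (data frame: `transcript_id`, `class`, `expressed_tissues`),
#'   `library_size` (named vector).
#' @export
simulate_expression <- function(sim, seed = 1L) {
  set.seed(seed + 1L)
  config <- sim$config
  ts <- sim$ts
  tt <- sim$truth$transcripts
  tissues <- config$tissues
  ids <- ts$tx$transcript_id
  n <- length(ids); m <- length(tissues)

  assembled <- matrix(FALSE, n, m, dimnames = list(ids, tissues))
  for (k in seq_len(n))
    assembled[k, split_tissues(ts$tx$tissues[k])[[1L]]] <- TRUE

  groups <- split(ids, tt$duplicate_group[match(ids, tt$transcript_id)])
  rpkm <- matrix(0.05, n, m, dimnames = list(ids, tissues))
  cls_by_tx <- stats::setNames(rep("broad", n), ids)
  expr_tis <- stats::setNames(rep("", n), ids)
  for (g in groups) {
    asm_union <- tissues[colSums(assembled[g, , drop = FALSE]) > 0]
    u <- stats::runif(1)
    cls <- if (length(asm_union) == 1L &&
               u < config$frac_tissue_specific) "tissue_specific"
    else if (u < config$frac_tissue_specific + config$frac_housekeeping)
      "housekeeping"
    else "broad"
    etis <- switch(cls,
      tissue_specific = asm_union,
      housekeeping = tissues,
      { extra <- max(0L, sample(2:max(2L, m - 2L), 1L) -
                       length(asm_union))
        sort(union(asm_union,
                   sample(setdiff(tissues, asm_union), extra))) })
    base <- switch(cls, tissue_specific = 30, housekeeping = 10, 8)
    rpkm[g, etis] <- base
    cls_by_tx[g] <- cls
    expr_tis[g] <- paste(etis, collapse = ",")
  }
  if (config$noise_sigma > 0) {
    noise <- matrix(exp(stats::rnorm(n * m, 0, config$noise_sigma)), n, m)
    rpkm <- rpkm * noise
    # clamp so planted expressed/not-expressed calls survive the noise
    planted_on <- matrix(FALSE, n, m, dimnames = list(ids, tissues))
    for (k in seq_len(n)) {
      et <- split_tissues(expr_tis[k])[[1L]]
      planted_on[k, et] <- TRUE
    }
    rpkm[planted_on] <- pmax(rpkm[planted_on], 2)
    rpkm[!planted_on] <- pmin(rpkm[!planted_on], 0.5)
  }

  libsize <- stats::setNames(rep(2e7, m), tissues)
  len <- spliced_length(ts)
  counts <- round(sweep(rpkm, 1L, len[ids] / 1e3, "*") *
                    (libsize[1L] / 1e6))
  jq <- matrix(stats::runif(n * m) < 0.7, n, m,
               dimnames = list(ids, tissues))
  for (k in seq_len(n))
    jq[k, split_tissues(expr_tis[k])[[1L]]] <- TRUE

  em <- expression_matrix(counts = counts, rpkm = rpkm,
                          assembled = assembled,
                          junctions_quantified = jq)
  list(em = em,
       truth_expression = data.frame(
         transcript_id = ids, class = unname(cls_by_tx[ids]),
         expressed_tissues = unname(expr_tis[ids]),
         stringsAsFactors = FALSE),
       library_size = libsize)
}

#' Simulate border- and promoter-evidence tracks
#'
#' Places a RAMPAGE peak inside the TSS validation window (30 bp 5' to
#' 10 bp 3' of the start site) of every transcript planted as
#' 5'-validated and a WTTS read inside the TTS window (10 bp 5' to 165
#' bp 3') of every 3'-validated transcript; unvalidated transcripts get
#' decoy evidence strictly outside every validation window. Single-exon
#' genes planted with promoter evidence get an H3K4me3 or ATAC peak in
#' their promoter; the rest get only a CTCF peak (which does not rescue
#' them).
#'
#' @param sim Output of [simulate_annotation()].
#' @param seed Integer seed.
#' @return Named list of `GRanges`: `RAMPAGE`, `WTTS`, `H3K4me3`,
#'   `H3K4me1`, `H3K27ac`, `ATAC`, `CTCF`.
#' @export
simulate_evidence <- function(sim, seed = 1L) {
  set.seed(seed + 2L)
  ts <- sim$ts
  tt <- sim$truth$transcripts
  tg <- sim$truth$genes
  chrom <- ts$tx$chrom[1L]
  i <- match(ts$tx$transcript_id, tt$transcript_id)
  v5 <- tt$validated5[i]; v3 <- tt$validated3[i]
  tss <- ts$tx$tss; tts <- ts$tx$tts
  plus <- ts$tx$strand == "+"

  ramp_s <- tss - 3L; ramp_e <- tss + 3L
  rampage <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(ramp_s[v5], ramp_e[v5]))
  wtts_s <- ifelse(plus, tts + 1L, tts - 150L)
  wtts_e <- ifelse(plus, tts + 150L, tts - 1L)
  wtts <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(wtts_s[v3], wtts_e[v3]))

  # decoys for unvalidated ends, dropped if they touch any validation
  # window (transcript- or gene-level)
  tss_win <- GenomicRanges::GRanges(chrom,
    .anchor_window(tss, ts$tx$strand, 30L, 10L))
  ga <- .feature_anchors(ts, "gene", "tss")
  tss_win <- c(tss_win, GenomicRanges::GRanges(chrom,
    .anchor_window(ga$pos, ga$strand, 30L, 10L)))
  tts_win <- GenomicRanges::GRanges(chrom,
    .anchor_window(tts, ts$tx$strand, 10L, 165L))
  gb <- .feature_anchors(ts, "gene", "tts")
  tts_win <- c(tts_win, GenomicRanges::GRanges(chrom,
    .anchor_window(gb$pos, gb$strand, 10L, 165L)))

  dec5 <- ifelse(plus, tss + 200L, tss - 220L)
  dec <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(dec5[!v5], dec5[!v5] + 20L))
  dec <- dec[GenomicRanges::countOverlaps(dec, tss_win) == 0]
  rampage <- sort(c(rampage, dec))
  dec3s <- ifelse(plus, tts + 400L, tts - 550L)
  dec3 <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(dec3s[!v3], dec3s[!v3] + 150L))
  dec3 <- dec3[GenomicRanges::countOverlaps(dec3, tts_win) == 0]
  wtts <- sort(c(wtts, dec3))

  tracks <- list(RAMPAGE = rampage, WTTS = wtts)
  se <- tg[tg$single_exon, , drop = FALSE]
  gtss <- stats::setNames(ga$pos, ga$feature_id)
  mk <- function(gids) {
    if (!length(gids)) return(GenomicRanges::GRanges())
    p <- gtss[gids]
    GenomicRanges::GRanges(chrom, IRanges::IRanges(p - 40L, p + 40L))
  }
  ev_g <- se$gene_id[se$promoter_evidence]
  half <- seq_along(ev_g) %% 2L == 0L
  tracks$H3K4me3 <- mk(ev_g[!half])
  tracks$ATAC <- mk(ev_g[half])
  tracks$H3K4me1 <- GenomicRanges::GRanges()
  tracks$H3K27ac <- GenomicRanges::GRanges()
  tracks$CTCF <- mk(se$gene_id[!se$promoter_evidence])
  for (nm in names(tracks))
    S4Vectors::metadata(tracks[[nm]])$track_name <- nm
  tracks
}

#' Simulate coverage and junction support tables
#'
#' Every transcript passes the default filters: coverage at least 3 in
#' each assembled tissue and every junction canonical with spanning
#' reads at 5-nt overhang.
#'
#' @param sim Output of [simulate_annotation()].
#' @param seed Integer seed.
#' @return A [support_tables()] object.
#' @export
simulate_support <- function(sim, seed = 1L) {
  set.seed(seed + 3L)
  ts <- sim$ts
  cov_rows <- list(); jn_rows <- list()
  for (k in seq_len(nrow(ts$tx))) {
    id <- ts$tx$transcript_id[k]
    tiss <- split_tissues(ts$tx$tissues[k])[[1L]]
    for (tis in tiss) {
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        transcript_id = id, tissue = tis,
        min_base_coverage = round(stats::runif(1, 3, 30), 1),
        stringsAsFactors = FALSE)
      jx <- tx_junctions(ts, id)
      if (nrow(jx))
        jn_rows[[length(jn_rows) + 1L]] <- data.frame(
          chrom = ts$tx$chrom[k], strand = ts$tx$strand[k],
          intron_start = jx[, 1L], intron_end = jx[, 2L], tissue = tis,
          reads = sample(2:40, nrow(jx), replace = TRUE),
          overhang = 5L, canonical = TRUE, stringsAsFactors = FALSE)
    }
  }
  junctions <- if (length(jn_rows)) do.call(rbind, jn_rows)
  else data.frame(chrom = character(0), strand = character(0),
                  intron_start = integer(0), intron_end = integer(0),
                  tissue = character(0), reads = integer(0),
                  overhang = integer(0), canonical = logical(0))
  support_tables(do.call(rbind, cov_rows), junctions)
}

#' Simulate a trait-QTL table with planted trait similarity
#'
#' Targets are drawn from genes whose spans overlap no other gene, so
#' nearest-gene assignment provably recovers the planted target. Planted
#' similar trait pairs share `similar_overlap` of their QTL-associated
#' genes; other traits draw independently. QTLs sit inside the target
#' gene body or 200-1000 bp away (well under half the intergenic gap).
#'
#' @param sim Output of [simulate_annotation()].
#' @param seed Integer seed.
#' @return List: `qtl` (data frame: `trait`, `qtl_id`, `chrom`,
#'   `start`, `end`), `truth_traits` (named list: trait -> planted gene
#'   set), `similar_pairs`.
#' @export
simulate_qtl_table <- function(sim, seed = 1L) {
  set.seed(seed + 4L)
  config <- sim$config
  tg <- sim$truth$genes
  spans <- gene_spans(sim$ts)
  # target pool: genes overlapping no other gene span
  ov <- GenomicRanges::countOverlaps(spans, spans, ignore.strand = TRUE)
  pool <- spans$gene_id[ov == 1L & spans$gene_id %in%
                          tg$gene_id[tg$class != "artifact"]]
  traits <- sprintf("trait%02d", seq_len(config$n_traits))
  nq <- config$qtls_per_trait
  if (length(pool) < nq)
    stop("config infeasible: not enough isolated genes for QTL targets")
  assoc <- list()
  for (tr in traits) assoc[[tr]] <- sort(sample(pool, nq))
  for (pr in config$similar_pairs) {
    n_share <- round(config$similar_overlap * nq)
    shared <- sample(assoc[[pr[1L]]], n_share)
    rest <- sample(setdiff(pool, shared), nq - n_share)
    assoc[[pr[2L]]] <- sort(c(shared, rest))
  }
  rows <- list()
  qi <- 0L
  for (tr in traits) for (g in assoc[[tr]]) {
    qi <- qi + 1L
    sp <- spans[spans$gene_id == g]
    s <- BiocGenerics::start(sp); e <- BiocGenerics::end(sp)
    if (stats::runif(1) < config$frac_qtl_inside) {
      qs <- s + 10L; qe <- min(e, qs + 400L)
    } else {
      d <- sample(200:1000, 1L)
      if (stats::runif(1) < 0.5) { qs <- e + d; qe <- qs + 80L }
      else { qe <- s - d; qs <- qe - 80L }
    }
    rows[[qi]] <- data.frame(
      trait = tr, qtl_id = sprintf("QTL%04d", qi),
      chrom = as.character(GenomeInfoDb::seqnames(sp)),
      start = qs, end = qe, stringsAsFactors = FALSE)
  }
  list(qtl = do.call(rbind, rows), truth_traits = assoc,
       similar_pairs = config$similar_pairs)
}

#' Simulate matched two-tissue expression for the axis correlation test
#'
#' Source and target gene sets share a latent per-sample factor when
#' `shared = TRUE` (positively correlated axis); the candidate pool is
#' always independent noise.
#'
#' @param n_source,n_target,n_pool Gene-set sizes.
#' @param n_samples Matched samples (animals).
#' @param shared Plant a shared latent factor between source and target.
#' @param loading Factor loading (default 0.8).
#' @param seed Integer seed.
#' @return List of matrices `source`, `target`, `pool` (genes x
#'   samples).
#' @export
simulate_axis_expression <- function(n_source = 62L, n_target = 246L,
                                     n_pool = 1000L, n_samples = 20L,
                                     shared = TRUE, loading = 0.8,
                                     seed = 1L) {
  set.seed(seed + 5L)
  f <- stats::rnorm(n_samples)
  mk <- function(ng, use_factor) {
    m <- matrix(stats::rnorm(ng * n_samples), ng, n_samples)
    if (use_factor)
      m <- loading * matrix(rep(f, each = ng), ng, n_samples) +
        sqrt(1 - loading^2) * m
    rownames(m) <- sprintf("g%04d", seq_len(ng))
    m
  }
  list(source = mk(n_source, shared),
       target = mk(n_target, shared),
       pool = mk(n_pool, FALSE))
}

#' Write a full simulation to disk
#'
#' Emits the catalogue GTF, reference GTF, genome FASTA, per-track
#' evidence BEDs, expression / support / homology / coding-potential /
#' QTL TSVs and a truth JSON, so every pipeline stage can be run from
#' files.
#'
#' @param sim Output of [simulate_annotation()].
#' @param dir Output directory (created if needed).
#' @param expression Optional output of [simulate_expression()].
#' @param evidence Optional output of [simulate_evidence()].
#' @param support Optional [support_tables()].
#' @param qtl Optional output of [simulate_qtl_table()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, expression = NULL,
                             evidence = NULL, support = NULL,
                             qtl = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(sim$ts, file.path(dir, "catalogue.gtf"))
  write_annotation(sim$reference, file.path(dir, "reference.gtf"))
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_tsv_table(sim$homology, file.path(dir, "homology.tsv"))
  write_tsv_table(
    data.frame(transcript_id = names(sim$coding_potential),
               is_coding = unname(sim$coding_potential)),
    file.path(dir, "coding_potential.tsv"))
  if (!is.null(evidence))
    for (nm in names(evidence))
      write_peaks(evidence[[nm]],
                  file.path(dir, paste0(tolower(nm), ".bed")))
  if (!is.null(expression)) {
    w <- function(m, f) {
      d <- data.frame(transcript_id = rownames(m), m,
                      check.names = FALSE)
      write_tsv_table(d, file.path(dir, f))
    }
    w(expression$em$counts, "counts.tsv")
    w(expression$em$rpkm, "rpkm.tsv")
    w(expression$em$assembled * 1L, "assembled.tsv")
    w(expression$em$junctions_quantified * 1L,
      "junctions_quantified.tsv")
  }
  if (!is.null(support)) {
    write_tsv_table(support$coverage, file.path(dir, "coverage.tsv"))
    write_tsv_table(support$junctions,
                    file.path(dir, "junction_support.tsv"))
  }
  if (!is.null(qtl))
    write_tsv_table(qtl$qtl, file.path(dir, "trait_qtl.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- sim$truth
    if (!is.null(qtl)) truth$traits <- qtl$truth_traits
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(dir)
}
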