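#' Biotype classification parameters
#'
#' @param min_orf_aa Representative ORFs strictly longer than this many
#'   amino acids are coding-capable (default 44; "longer than" is strict).
#' @param nmd_dist_nt An ORF stop strictly more than this many spliced
#'   nucleotides upstream of the final exon-exon junction marks
#'   nonsense-mediated decay (default 50).
#' @param snc_max_nt Noncoding transcripts strictly shorter than this are
#'   small noncoding RNA candidates; length at or above it gives a lncRNA
#'   (default 200; exactly 200 nt is assigned to lncRNA).
#' @param evalue_max,min_cov,min_ident Protein-homology thresholds for
#'   representative-ORF selection.
#' @param nuc_min_cov,nuc_min_ident Nucleotide-homology thresholds for the
#'   pseudogene rule (coverage 90, identity 95).
#' @return List of parameters.
#' @export
biotype_params <- function(min_orf_aa = 44L, nmd_dist_nt = 50L,
                           snc_max_nt = 200L, evalue_max = 1e-6,
                           min_cov = 60, min_ident = 95,
                           nuc_min_cov = 90, nuc_min_ident = 95) {
  list(min_orf_aa = min_orf_aa, nmd_dist_nt = nmd_dist_nt,
       snc_max_nt = snc_max_nt, evalue_max = evalue_max,
       min_cov = min_cov, min_ident = min_ident,
       nuc_min_cov = nuc_min_cov, nuc_min_ident = nuc_min_ident)
}

# Spliced-coordinate position of the final exon-exon junction: the last
# transcribed base before the 3'-most exon. NA for unspliced transcripts.
final_junction_spliced_pos <- function(ts, id) {
  ex <- tx_exons(ts, id)
  if (length(ex) < 2L) return(NA_integer_)
  w <- BiocGenerics::width(ex)
  if (as.character(BiocGenerics::strand(ex))[1L] == "+")
    sum(w[-length(w)])
  else
    sum(w[-1L])
}

#' Index of protein-coding gene structures for lncRNA subtyping
#'
#' @param ts A `tx_set`.
#' @param coding_gene_ids Gene ids holding at least one protein-coding
#'   transcript.
#' @return List with `spans` (per-gene `GRanges`), `exons` (exon
#'   `GRanges` with `gene_id`), and `introns` (intronic blocks per gene:
#'   gene span minus exonic union).
#' @export
coding_gene_index <- function(ts, coding_gene_ids) {
  tx <- ts$tx[ts$tx$gene_id %in% coding_gene_ids, , drop = FALSE]
  ex <- ts$exons[ts$exons$transcript_id %in% tx$transcript_id]
  gid <- tx$gene_id[match(ex$transcript_id, tx$transcript_id)]
  ex2 <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(ex),
                                IRanges::ranges(ex),
                                strand = BiocGenerics::strand(ex),
                                gene_id = gid)
  agg <- unique(tx[, c("gene_id", "chrom", "strand")])
  s <- tapply(tx$start, tx$gene_id, min)[agg$gene_id]
  e <- tapply(tx$end, tx$gene_id, max)[agg$gene_id]
  spans <- GenomicRanges::GRanges(agg$chrom,
                                  IRanges::IRanges(as.integer(s),
                                                   as.integer(e)),
                                  strand = agg$strand,
                                  gene_id = agg$gene_id)
  introns <- lapply(seq_along(spans), function(i) {
    g <- spans$gene_id[i]
    exg <- GenomicRanges::reduce(ex2[ex2$gene_id == g])
    gaps <- GenomicRanges::setdiff(spans[i], exg)
    gaps$gene_id <- rep(g, length(gaps))
    gaps
  })
  introns <- if (length(introns)) do.call(c, introns)
  else GenomicRanges::GRanges()
  list(spans = spans, exons = ex2, introns = introns)
}

#' Subtype a long noncoding RNA relative to coding loci
#'
#' Precedence: antisense (any exon overlaps a coding gene span on the
#' opposite strand) > sense-intronic (whole transcript inside one intronic
#' block of a same-strand coding gene) > intragenic (an exon overlaps a
#' same-strand coding gene's exons) > intergenic.
#'
#' @param ts A `tx_set`.
#' @param id Transcript id.
#' @param coding Index from [coding_gene_index()].
#' @return One of `"lncRNA_antisense"`, `"lncRNA_sense_intronic"`,
#'   `"lncRNA_intragenic"`, `"lncRNA_intergenic"`.
#' @export
classify_lncrna_subtype <- function(ts, id, coding) {
  ex <- tx_exons(ts, id)
  if (is.null(coding) || length(coding$spans) == 0L)
    return("lncRNA_intergenic")
  # exclude the transcript's own locus from "coding gene" comparisons
  own_gene <- ts$tx[id, "gene_id"]
  keep_span <- coding$spans$gene_id != own_gene
  spans <- coding$spans[keep_span]
  exons <- coding$exons[coding$exons$gene_id != own_gene]
  introns <- coding$introns[coding$introns$gene_id != own_gene]

  flip <- function(gr) {
    s <- as.character(BiocGenerics::strand(gr))
    BiocGenerics::strand(gr) <- ifelse(s == "+", "-", "+")
    gr
  }
  if (length(spans) &&
      any(GenomicRanges::countOverlaps(ex, flip(spans)) > 0))
    return("lncRNA_antisense")
  span <- GenomicRanges::GRanges(
    ts$tx[id, "chrom"],
    IRanges::IRanges(ts$tx[id, "start"], ts$tx[id, "end"]),
    strand = ts$tx[id, "strand"])
  if (length(introns)) {
    within <- GenomicRanges::findOverlaps(span, introns, type = "within")
    if (length(within)) return("lncRNA_sense_intronic")
  }
  if (length(exons) &&
      any(GenomicRanges::countOverlaps(ex, exons) > 0))
    return("lncRNA_intragenic")
  "lncRNA_intergenic"
}

#' Classify one transcript's biotype
#'
#' Decision tree: a representative ORF with a stop codon and strictly more
#' than `min_orf_aa` amino acids is coding-capable -- nonsense-mediated
#' decay (nmd) when its stop lies strictly more than `nmd_dist_nt` spliced
#' nucleotides upstream of the final exon-exon junction, protein_coding
#' otherwise (unspliced transcripts can never be nmd). A representative
#' ORF with a start but no stop codon is nonstop decay (nsd). Remaining
#' transcripts are noncoding: shorter than `snc_max_nt` with no external
#' coding-potential call and no miRNA-precursor overlap gives sncRNA;
#' otherwise a lncRNA subtype via [classify_lncrna_subtype()].
#'
#' @param ts A `tx_set`.
#' @param id Transcript id.
#' @param rep_orf Representative ORF row from
#'   [select_representative_orf()], or `NULL`.
#' @param coding_potential External coding-potential flag for this
#'   transcript (consulted only in the noncoding branch).
#' @param mirna_precursors `GRanges` of miRNA precursor intervals, or
#'   `NULL`.
#' @param coding Index from [coding_gene_index()], or `NULL`.
#' @param params [biotype_params()].
#' @return List with `label`, `fired_rule`, `representative_orf`.
#' @export
classify_transcript <- function(ts, id, rep_orf, coding_potential = FALSE,
                                mirna_precursors = NULL, coding = NULL,
                                params = biotype_params()) {
  spliced_len <- sum(BiocGenerics::width(tx_exons(ts, id)))
  if (!is.null(rep_orf) && nrow(rep_orf)) {
    if (rep_orf$has_stop && rep_orf$length_aa > params$min_orf_aa) {
      fj <- final_junction_spliced_pos(ts, id)
      if (!is.na(fj)) {
        dist <- fj - rep_orf$stop_end
        if (dist > params$nmd_dist_nt)
          return(list(label = "nmd",
                      fired_rule = sprintf(
                        "stop %d nt upstream of final junction (> %d)",
                        dist, params$nmd_dist_nt),
                      representative_orf = rep_orf))
      }
      return(list(label = "protein_coding",
                  fired_rule = sprintf("representative ORF %d aa (> %d)",
                                       rep_orf$length_aa,
                                       params$min_orf_aa),
                  representative_orf = rep_orf))
    }
    if (!rep_orf$has_stop)
      return(list(label = "nsd",
                  fired_rule = "start codon, no stop before poly(A) site",
                  representative_orf = rep_orf))
  }
  # noncoding branch
  has_mirna <- FALSE
  if (!is.null(mirna_precursors) && length(mirna_precursors)) {
    ex <- tx_exons(ts, id)
    mp <- mirna_precursors
    BiocGenerics::strand(mp) <- "*"
    ex2 <- ex; BiocGenerics::strand(ex2) <- "*"
    has_mirna <- any(GenomicRanges::countOverlaps(ex2, mp) > 0)
  }
  if (spliced_len < params$snc_max_nt && !coding_potential && !has_mirna)
    return(list(label = "sncRNA",
                fired_rule = sprintf("noncoding, %d nt (< %d), no miRNA overlap",
                                     spliced_len, params$snc_max_nt),
                representative_orf = rep_orf))
  sub <- classify_lncrna_subtype(ts, id, coding)
  rule <- if (spliced_len < params$snc_max_nt)
    "short noncoding failing sncRNA criteria, assigned lncRNA subtype"
  else sprintf("noncoding, %d nt (>= %d)", spliced_len, params$snc_max_nt)
  list(label = sub, fired_rule = rule, representative_orf = rep_orf)
}

#' Classify every transcript and gene in a set
#'
#' Runs ORF finding on the spliced sequences, selects representative ORFs
#' against the protein-homology table, applies the transcript decision
#' tree in two passes (core labels, then lncRNA subtypes against the
#' coding loci found in pass one), and derives gene-level biotypes.
#'
#' @param ts A `tx_set`.
#' @param genome Named `DNAStringSet`.
#' @param homology Homology table (protein and nucleotide rows), or
#'   `NULL`.
#' @param coding_potential Named logical vector (transcript id ->
#'   external coding-potential flag), or `NULL` (all `FALSE`).
#' @param mirna_precursors `GRanges` of miRNA precursors, or `NULL`.
#' @param params [biotype_params()].
#' @param allow_alternative_starts Passed to [find_orfs()].
#' @return List with `transcripts` (data frame: `transcript_id`,
#'   `gene_id`, `label`, `fired_rule`, `orf_length_aa`, `orf_has_stop`)
#'   and `genes` (data frame from [classify_gene()]).
#' @export
classify_transcripts <- function(ts, genome, homology = NULL,
                                 coding_potential = NULL,
                                 mirna_precursors = NULL,
                                 params = biotype_params(),
                                 allow_alternative_starts = TRUE) {
  ids <- ts$tx$transcript_id
  seqs <- tx_seq(ts, genome)
  cp <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(coding_potential))
    cp[names(coding_potential)] <- coding_potential

  reps <- stats::setNames(vector("list", length(ids)), ids)
  core <- character(length(ids)); names(core) <- ids
  for (id in ids) {
    orfs <- find_orfs(seqs[[id]], transcript_id = id,
                      allow_alternative_starts = allow_alternative_starts)
    reps[[id]] <- select_representative_orf(
      orfs, homology, evalue_max = params$evalue_max,
      min_cov = params$min_cov, min_ident = params$min_ident)
    cl <- classify_transcript(ts, id, reps[[id]], coding_potential = cp[[id]],
                              mirna_precursors = mirna_precursors,
                              coding = NULL, params = params)
    core[id] <- cl$label
  }
  # pass 2: lncRNA subtypes against coding loci found in pass 1
  coding_gids <- unique(ts$tx$gene_id[core[ids] == "protein_coding"])
  cindex <- if (length(coding_gids)) coding_gene_index(ts, coding_gids)
  else NULL
  out <- data.frame(transcript_id = ids,
                    gene_id = ts$tx[ids, "gene_id"],
                    label = NA_character_, fired_rule = NA_character_,
                    orf_length_aa = NA_integer_, orf_has_stop = NA,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    id <- ids[k]
    cl <- classify_transcript(ts, id, reps[[id]], coding_potential = cp[[id]],
                              mirna_precursors = mirna_precursors,
                              coding = cindex, params = params)
    out$label[k] <- cl$label
    out$fired_rule[k] <- cl$fired_rule
    if (!is.null(cl$representative_orf) && nrow(cl$representative_orf)) {
      out$orf_length_aa[k] <- cl$representative_orf$length_aa
      out$orf_has_stop[k] <- cl$representative_orf$has_stop
    }
  }
  genes <- classify_gene(out, homology, params = params)
  list(transcripts = out, genes = genes)
}

#' Gene-level biotype from transcript labels
#'
#' A gene with at least one protein-coding transcript is protein-coding.
#' A gene whose transcripts are all nmd/nsd and that carries a passing
#' nucleotide-homology hit to a vertebrate protein-coding gene (disrupted
#' coding sequence) is a pseudogene; the rest are noncoding. lncRNAs
#' transcribed from pseudogene loci are flagged.
#'
#' @param tx_biotypes Transcript table from [classify_transcripts()].
#' @param homology Homology table with nucleotide rows keyed by gene id
#'   (or any of the gene's transcript ids), or `NULL`.
#' @param params [biotype_params()].
#' @return Data frame: `gene_id`, `label`, `pseudogene_derived_lncRNA`.
#' @export
classify_gene <- function(tx_biotypes, homology = NULL,
                          params = biotype_params()) {
  if (nrow(tx_biotypes) == 0L)
    return(data.frame(gene_id = character(0), label = character(0),
                      pseudogene_derived_lncRNA = logical(0)))
  split_lab <- split(tx_biotypes$label, tx_biotypes$gene_id)
  split_tid <- split(tx_biotypes$transcript_id, tx_biotypes$gene_id)
  gids <- names(split_lab)
  nuc_hit <- rep(FALSE, length(gids)); names(nuc_hit) <- gids
  if (!is.null(homology) && nrow(homology)) {
    h <- homology[homology$search_kind == "nucleotide" &
                    homology$evalue <= params$evalue_max &
                    homology$coverage_pct >= params$nuc_min_cov &
                    homology$identity_pct >= params$nuc_min_ident, ,
                  drop = FALSE]
    for (g in gids)
      nuc_hit[g] <- any(h$query_id %in% c(g, split_tid[[g]]))
  }
  lab <- vapply(gids, function(g) {
    ls <- split_lab[[g]]
    if (length(ls) == 0L) stop("gene with zero classified transcripts: ", g)
    if (any(ls == "protein_coding")) return("protein_coding")
    if (all(ls %in% c("nmd", "nsd")) && nuc_hit[g]) return("pseudogene")
    "noncoding"
  }, "")
  pderived <- vapply(gids, function(g) {
    lab[g] == "pseudogene" || (nuc_hit[g] &&
      any(grepl("^lncRNA", split_lab[[g]])) &&
      all(split_lab[[g]] %in%
            c("nmd", "nsd", grep("^lncRNA", split_lab[[g]], value = TRUE))))
  }, TRUE)
  pderived <- pderived & vapply(gids, function(g)
    any(grepl("^lncRNA", split_lab[[g]])), TRUE)
  data.frame(gene_id = gids, label = unname(lab),
             pseudogene_derived_lncRNA = unname(pderived),
             stringsAsFactors = FALSE)
}

#' Bifunctional, PAT and coding/noncoding switch flags per gene
#'
#' Per tissue, a gene is bifunctional when it expresses at least one
#' protein-coding and at least one non-protein-coding transcript. A PAT
#' gene expresses at least one potentially aberrant transcript (nmd or
#' nsd); PATs are a gene's main transcripts in a tissue when they make up
#' strictly more than half of its expressed transcripts there. A switch
#' gene is noncoding-only in some expressed tissue and coding in another.
#'
#' @param tx_biotypes Transcript table from [classify_transcripts()].
#' @param expressed Logical matrix, transcripts x tissues (dimnames
#'   required), from [mark_expressed()].
#' @return List with `per_tissue` (data frame: gene_id, tissue,
#'   n_expressed, n_coding, n_pat, bifunctional, pat_main) and `genes`
#'   (data frame: gene_id, pat_gene, bifunctional_any, switch_gene).
#' @export
flag_bifunctional_and_pat <- function(tx_biotypes, expressed) {
  stopifnot(!is.null(rownames(expressed)), !is.null(colnames(expressed)))
  bt <- tx_biotypes[tx_biotypes$transcript_id %in% rownames(expressed), ,
                    drop = FALSE]
  tissues <- colnames(expressed)
  rows <- list()
  for (g in unique(bt$gene_id)) {
    tids <- bt$transcript_id[bt$gene_id == g]
    lab <- stats::setNames(bt$label[bt$gene_id == g], tids)
    for (tis in tissues) {
      expr <- tids[expressed[tids, tis]]
      if (!length(expr)) next
      n_cod <- sum(lab[expr] == "protein_coding")
      n_pat <- sum(lab[expr] %in% c("nmd", "nsd"))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, tissue = tis, n_expressed = length(expr),
        n_coding = n_cod, n_pat = n_pat,
        bifunctional = n_cod >= 1L && (length(expr) - n_cod) >= 1L,
        pat_main = n_pat / length(expr) > 0.5,
        stringsAsFactors = FALSE)
    }
  }
  per_tissue <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene_id = character(0), tissue = character(0),
                  n_expressed = integer(0), n_coding = integer(0),
                  n_pat = integer(0), bifunctional = logical(0),
                  pat_main = logical(0))
  genes <- do.call(rbind, lapply(split(per_tissue, per_tissue$gene_id),
    function(d) data.frame(
      gene_id = d$gene_id[1L],
      pat_gene = any(d$n_pat >= 1L),
      bifunctional_any = any(d$bifunctional),
      switch_gene = any(d$n_coding == 0L) && any(d$n_coding >= 1L),
      stringsAsFactors = FALSE)))
  if (is.null(genes))
    genes <- data.frame(gene_id = character(0), pat_gene = logical(0),
                        bifunctional_any = logical(0),
                        switch_gene = logical(0))
  rownames(genes) <- NULL
  list(per_tissue = per_tissue, genes = genes)
}
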