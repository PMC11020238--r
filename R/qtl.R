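#' Nearest expressed gene to a QTL interval
#'
#' Distance is 0 when the QTL overlaps the gene span; otherwise the gap
#' between the closest interval boundaries, on either side. Ties are
#' broken by the lexicographically smaller gene id.
#'
#' @param chrom,start,end QTL interval (1-based closed).
#' @param genes `GRanges` of expressed gene spans with a `gene_id`
#'   metadata column.
#' @return List with `gene_id` and `distance_nt`, or `NULL` when no gene
#'   lies on the QTL's chromosome.
#' @export
nearest_expressed_gene <- function(chrom, start, end, genes) {
  g <- genes[as.character(GenomeInfoDb::seqnames(genes)) == chrom]
  if (!length(g)) return(NULL)
  gs <- BiocGenerics::start(g); ge <- BiocGenerics::end(g)
  d <- ifelse(ge < start, start - ge,
              ifelse(gs > end, gs - end, 0L))
  best <- min(d)
  cand <- g$gene_id[d == best]
  list(gene_id = sort(cand)[1L], distance_nt = as.integer(best))
}

#' QTL-associated genes per trait
#'
#' Assigns every QTL its nearest expressed gene and collects, per trait,
#' the set of QTL-associated genes.
#'
#' @param qtl Data frame: `trait`, `qtl_id`, `chrom`, `start`, `end`
#'   (1-based closed).
#' @param genes `GRanges` of expressed gene spans with `gene_id`.
#' @return List with `assignments` (data frame: `trait`, `qtl_id`,
#'   `gene_id`, `distance_nt`) and `assoc` (named list: trait -> unique
#'   gene ids).
#' @export
assign_qtl_genes <- function(qtl, genes) {
  rows <- lapply(seq_len(nrow(qtl)), function(i) {
    hit <- nearest_expressed_gene(qtl$chrom[i], qtl$start[i], qtl$end[i],
                                  genes)
    if (is.null(hit)) {
      message("no expressed gene on chromosome ", qtl$chrom[i],
              " for QTL ", qtl$qtl_id[i])
      return(NULL)
    }
    data.frame(trait = qtl$trait[i], qtl_id = qtl$qtl_id[i],
               gene_id = hit$gene_id, distance_nt = hit$distance_nt,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  assignments <- if (length(rows)) do.call(rbind, rows)
  else data.frame(trait = character(0), qtl_id = character(0),
                  gene_id = character(0), distance_nt = integer(0))
  assoc <- lapply(split(assignments$gene_id, assignments$trait), unique)
  list(assignments = assignments, assoc = assoc)
}

#' Right-sided Fisher enrichment of a gene set in trait-associated genes
#'
#' For each trait, tests whether `gene_set` overlaps the trait's
#' QTL-associated genes more than expected from the expressed-gene
#' universe (right-sided Fisher exact test, i.e. the hypergeometric upper
#' tail), with Benjamini-Hochberg correction across traits.
#'
#' @param gene_set Character vector, a subset of `universe`.
#' @param assoc Named list: trait -> associated gene ids.
#' @param universe All expressed genes eligible as nearest neighbours.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return Data frame: `trait`, `overlap`, `n_trait_genes`, `p`, `adj_p`,
#'   `enriched`.
#' @export
qtl_enrichment <- function(gene_set, assoc, universe, alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  gene_set <- intersect(gene_set, universe)
  N <- length(universe); n <- length(gene_set)
  res <- do.call(rbind, lapply(names(assoc), function(tr) {
    K <- length(intersect(assoc[[tr]], universe))
    k <- length(intersect(assoc[[tr]], gene_set))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(trait = tr, overlap = k, n_trait_genes = K, p = p,
               stringsAsFactors = FALSE)
  }))
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res$enriched <- res$adj_p < alpha
  res
}

#' Permutation test of directed trait similarity
#'
#' Trait A is similar to trait B when the observed overlap between A's
#' QTL-associated genes and B's exceeds what random gene sets of B's size
#' achieve: the null resamples `n_perm` gene sets of size `|assoc(B)|`
#' without replacement from the expressed-gene universe, and
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param genes_a,genes_b QTL-associated gene sets of the two traits.
#' @param universe Expressed-gene universe to resample from.
#' @param n_perm Number of permutations (default 1000).
#' @return List with `observed_overlap` and `perm_p`.
#' @export
trait_similarity <- function(genes_a, genes_b, universe, n_perm = 1000L) {
  stopifnot(length(genes_a) >= 1L, length(genes_b) >= 1L)
  m <- length(genes_b)
  N <- length(universe)
  if (m > N) stop("trait gene set larger than universe")
  in_a <- universe %in% genes_a
  obs <- length(intersect(genes_a, genes_b))
  # every resampled overlap is >= 0, so an observed overlap of zero has
  # p = (1 + n_perm) / (n_perm + 1) = 1 exactly; skip the draws
  if (obs == 0L)
    return(list(observed_overlap = 0L, perm_p = 1))
  null <- vapply(seq_len(n_perm), function(i)
    sum(in_a[sample.int(N, m)]), 0L)
  list(observed_overlap = obs,
       perm_p = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Permutation trait-similarity network
#'
#' Runs [trait_similarity()] for every ordered trait pair, applies
#' Benjamini-Hochberg correction over all directional tests, and keeps
#' the edges significant at `alpha`. An undirected pair is reported
#' connected when either direction is significant; both directional
#' p-values are retained.
#'
#' @param assoc Named list: trait -> QTL-associated gene ids.
#' @param universe Expressed-gene universe.
#' @param n_perm Permutations per test (default 1000).
#' @param alpha BH-adjusted threshold (default 0.05).
#' @param seed Optional RNG seed for reproducible networks.
#' @return List with `tests` (all directional tests: `trait_a`,
#'   `trait_b`, `observed_overlap`, `perm_p`, `adj_p`, `significant`) and
#'   `edges` (unordered significant pairs with both directions' adjusted
#'   p-values).
#' @export
build_trait_network <- function(assoc, universe, n_perm = 1000L,
                                alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traits <- names(assoc)
  if (length(traits) < 2L)
    return(list(tests = data.frame(), edges = data.frame()))
  pairs <- expand.grid(a = traits, b = traits, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  tests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    r <- trait_similarity(assoc[[pairs$a[i]]], assoc[[pairs$b[i]]],
                          universe, n_perm)
    data.frame(trait_a = pairs$a[i], trait_b = pairs$b[i],
               observed_overlap = r$observed_overlap, perm_p = r$perm_p,
               stringsAsFactors = FALSE)
  }))
  tests$adj_p <- stats::p.adjust(tests$perm_p, method = "BH")
  tests$significant <- tests$adj_p < alpha
  key <- apply(cbind(tests$trait_a, tests$trait_b), 1L,
               function(x) paste(sort(x), collapse = "\r"))
  sig_keys <- unique(key[tests$significant])
  edges <- do.call(rbind, lapply(sig_keys, function(k) {
    ab <- strsplit(k, "\r")[[1L]]
    fwd <- tests[tests$trait_a == ab[1L] & tests$trait_b == ab[2L], ]
    rev <- tests[tests$trait_a == ab[2L] & tests$trait_b == ab[1L], ]
    data.frame(trait_a = ab[1L], trait_b = ab[2L],
               adj_p_ab = fwd$adj_p, adj_p_ba = rev$adj_p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(trait_a = character(0), trait_b = character(0),
                        adj_p_ab = numeric(0), adj_p_ba = numeric(0))
  list(tests = tests, edges = edges)
}

#' Tissue-axis expression-correlation significance test
#'
#' Computes all pairwise Spearman correlations between a source gene set
#' and a target gene set across matched samples (the reference
#' correlations), then draws `n_random` random gene sets of the target's
#' size from a candidate pool, recomputes the correlations per draw, and
#' compares reference vs draw with a right-sided two-sample t-test. The
#' `n_random` p-values are Benjamini-Hochberg adjusted and their
#' distribution is the significance summary.
#'
#' @param expr_source Numeric matrix, source genes x samples.
#' @param expr_target Numeric matrix, target genes x samples (same
#'   sample columns).
#' @param expr_pool Numeric matrix, candidate pool genes x samples, to
#'   draw random target sets from.
#' @param n_random Number of random target sets (default 1000); 0
#'   returns the reference correlations only.
#' @param seed Optional RNG seed.
#' @return List with `reference_correlations`, `adj_p` (length
#'   `n_random`, or `NULL`), and `frac_significant` (share of adjusted
#'   p-values below 0.05, or `NA`).
#' @export
axis_correlation_test <- function(expr_source, expr_target, expr_pool,
                                  n_random = 1000L, seed = NULL) {
  if (ncol(expr_source) < 3L || ncol(expr_source) != ncol(expr_target))
    stop("need >= 3 matched samples across the two tissues")
  if (!is.null(seed)) set.seed(seed)
  ref <- as.vector(stats::cor(t(expr_source), t(expr_target),
                              method = "spearman"))
  if (n_random == 0L)
    return(list(reference_correlations = ref, adj_p = NULL,
                frac_significant = NA_real_))
  m <- nrow(expr_target)
  if (m > nrow(expr_pool)) stop("target set larger than candidate pool")
  p <- vapply(seq_len(n_random), function(i) {
    draw <- expr_pool[sample.int(nrow(expr_pool), m), , drop = FALSE]
    rnd <- as.vector(stats::cor(t(expr_source), t(draw),
                                method = "spearman"))
    stats::t.test(ref, rnd, alternative = "greater")$p.value
  }, 0)
  adj <- stats::p.adjust(p, method = "BH")
  list(reference_correlations = ref, adj_p = adj,
       frac_significant = mean(adj < 0.05))
}
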