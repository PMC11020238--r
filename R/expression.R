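#' Feature-by-tissue expression container
#'
#' @param counts Integer matrix, features x tissues (dimnames required).
#' @param rpkm Numeric matrix of the same shape.
#' @param assembled Logical matrix: feature assembled from reads in that
#'   tissue.
#' @param junctions_quantified Logical matrix: all of the feature's
#'   splice junctions quantified in that tissue (always `TRUE` for
#'   unspliced features).
#' @return List of the four matrices, class `expr_matrix`.
#' @export
expression_matrix <- function(counts, rpkm, assembled,
                              junctions_quantified) {
  dims <- dim(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            identical(dim(rpkm), dims), identical(dim(assembled), dims),
            identical(dim(junctions_quantified), dims),
            all(counts >= 0), all(rpkm >= 0))
  structure(list(counts = counts, rpkm = rpkm, assembled = assembled,
                 junctions_quantified = junctions_quantified),
            class = "expr_matrix")
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param counts Integer matrix, features x tissues.
#' @param length_nt Named numeric vector of feature lengths in
#'   nucleotides (spliced lengths for transcripts).
#' @param library_size Named numeric vector of mapped reads per tissue.
#' @return RPKM matrix.
#' @export
compute_rpkm <- function(counts, length_nt, library_size) {
  stopifnot(all(length_nt > 0), all(library_size > 0))
  len <- length_nt[rownames(counts)]
  lib <- library_size[colnames(counts)]
  if (anyNA(len)) stop("missing transcript length")
  if (anyNA(lib)) stop("missing library size")
  sweep(sweep(counts, 1L, len / 1e3, "/"), 2L, lib / 1e6, "/")
}

#' Mark features as expressed per tissue
#'
#' A transcript is expressed in a tissue iff it was assembled there, or
#' its abundance exceeds `rpkm_threshold` (strictly) with all of its
#' splice junctions quantified in that tissue.
#'
#' @param em An [expression_matrix()].
#' @param rpkm_threshold Strict RPKM cutoff (default 1).
#' @return Logical matrix, features x tissues.
#' @export
mark_expressed <- function(em, rpkm_threshold = 1) {
  stopifnot(inherits(em, "expr_matrix"))
  em$assembled | (em$rpkm > rpkm_threshold & em$junctions_quantified)
}

#' Roll transcript-level expression calls up to genes
#'
#' A gene is expressed in a tissue iff at least one of its transcripts
#' is.
#'
#' @param expressed Logical matrix, transcripts x tissues.
#' @param gene_id Named character vector mapping transcript id to gene
#'   id.
#' @return Logical matrix, genes x tissues.
#' @export
gene_expressed <- function(expressed, gene_id) {
  g <- gene_id[rownames(expressed)]
  if (anyNA(g)) stop("missing gene assignment for some transcripts")
  rows <- rowsum((expressed) * 1L, g)
  (rows > 0)
}

#' Tissue Specificity Index
#'
#' `TSI = sum(1 - x_i) / (N - 1)` where `x` is the expression vector
#' max-normalised over all `N` tissues. 0 marks a uniformly expressed
#' housekeeper, 1 a feature expressed in a single tissue.
#'
#' @param v Nonnegative expression vector over N >= 2 tissues.
#' @return TSI in `[0, 1]`, or `NA` with a warning for an all-zero
#'   vector.
#' @export
compute_tsi <- function(v) {
  stopifnot(length(v) >= 2L, all(v >= 0))
  m <- max(v)
  if (m == 0) {
    warning("all-zero expression vector: TSI undefined")
    return(NA_real_)
  }
  sum(1 - v / m) / (length(v) - 1L)
}

#' TSI for every row of an expression matrix
#'
#' @param rpkm Numeric matrix, features x tissues.
#' @param expressed Optional logical matrix used to count expressed
#'   tissues per feature.
#' @return Data frame: `feature_id`, `tsi`, `n_tissues_expressed`.
#' @export
tsi_table <- function(rpkm, expressed = NULL) {
  tsi <- apply(rpkm, 1L, function(v)
    if (max(v) == 0) NA_real_ else sum(1 - v / max(v)) / (ncol(rpkm) - 1L))
  n_ex <- if (!is.null(expressed)) rowSums(expressed[rownames(rpkm), ,
                                                     drop = FALSE])
  else rowSums(rpkm > 0)
  data.frame(feature_id = rownames(rpkm), tsi = unname(tsi),
             n_tissues_expressed = unname(n_ex),
             stringsAsFactors = FALSE)
}

#' Tissue-specificity classes
#'
#' Features expressed in exactly one tissue are `tissue_specific`;
#' multi-tissue features with TSI strictly above `tsi_cut` are expressed
#' in a `tissue_specific_manner`; the rest are `broad`.
#'
#' @param expressed Logical matrix, features x tissues.
#' @param tsi Data frame from [tsi_table()].
#' @param tsi_cut Strict TSI cutoff (default 0.9).
#' @return Data frame: `feature_id`, `class`.
#' @export
classify_specificity <- function(expressed, tsi, tsi_cut = 0.9) {
  n_tis <- rowSums(expressed)[tsi$feature_id]
  cls <- ifelse(n_tis == 1L, "tissue_specific",
                ifelse(n_tis >= 2L & !is.na(tsi$tsi) & tsi$tsi > tsi_cut,
                       "tissue_specific_manner", "broad"))
  data.frame(feature_id = tsi$feature_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Pairwise tissue sharing of expressed features
#'
#' `sharing(i, j) = 100 * |A_i intersect A_j| / min(|A_i|, |A_j|)` by
#' default (`method = "min"`), or the Jaccard percentage
#' (`method = "jaccard"`), where `A_i` is the set of features expressed
#' in tissue i.
#'
#' @param expressed Logical matrix, features x tissues.
#' @param method `"min"` or `"jaccard"`.
#' @return Symmetric numeric matrix of sharing percentages (100 on the
#'   diagonal). Tissues with zero expressed features are dropped with a
#'   warning.
#' @export
tissue_sharing <- function(expressed, method = c("min", "jaccard")) {
  method <- match.arg(method)
  sizes <- colSums(expressed)
  if (any(sizes == 0)) {
    warning("dropping tissues with zero expressed features: ",
            paste(colnames(expressed)[sizes == 0], collapse = ", "))
    expressed <- expressed[, sizes > 0, drop = FALSE]
  }
  m <- crossprod(expressed * 1L)   # pairwise intersection sizes
  sz <- diag(m)
  denom <- if (method == "min") outer(sz, sz, pmin)
  else outer(sz, sz, "+") - m
  100 * m / denom
}

#' Cluster tissues on sharing and compare dendrograms
#'
#' Hierarchical clustering on `100 - sharing` as distance; dendrogram
#' similarity is the Spearman correlation between the two trees'
#' cophenetic distance vectors (leaves matched by name).
#'
#' @param sharing Sharing matrix from [tissue_sharing()].
#' @param linkage `hclust` agglomeration method (default `"complete"`).
#' @return An `hclust` object.
#' @export
cluster_tissues <- function(sharing, linkage = "complete") {
  stopifnot(nrow(sharing) >= 3L)
  stats::hclust(stats::as.dist(100 - sharing), method = linkage)
}

#' @rdname cluster_tissues
#' @param h1,h2 `hclust` objects over the same leaf labels.
#' @return `compare_dendrograms`: Spearman correlation of cophenetic
#'   distances.
#' @export
compare_dendrograms <- function(h1, h2) {
  c1 <- as.matrix(stats::cophenetic(h1))
  c2 <- as.matrix(stats::cophenetic(h2))
  common <- intersect(rownames(c1), rownames(c2))
  if (length(common) < 3L) stop("need >= 3 shared leaves")
  lt <- lower.tri(c1[common, common])
  stats::cor(c1[common, common][lt], c2[common, common][lt],
             method = "spearman")
}

#' Write a tissue dendrogram as newick
#' @param h An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), path)
  invisible(path)
}
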