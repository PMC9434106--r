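#' Patristic (cophenetic) distances between tree tips
#'
#' The distance between two tips is the sum of branch lengths along the path
#' connecting them.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames, zero
#'   diagonal.
#' @export
cophenetic_distances <- function(tree) {
  tree <- validate_tree(tree)
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 tips")
  D <- stats::cophenetic(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Per-sample relative abundances
#'
#' @param table an [otu_table].
#' @return numeric matrix of the same shape whose rows each sum to 1.
#' @export
relative_abundances <- function(table) {
  counts <- .otu_counts(as_otu_table(table))
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop(sprintf("sample '%s' has zero total abundance",
                 rownames(counts)[totals == 0][1]))
  counts / totals
}

# betaMNTD for one sample pair.
#   wa, wb : weights of the taxa present in a / b (already normalized)
#   ia, ib : patristic-matrix row indices of those taxa (possibly permuted
#            for a tip-shuffle null draw)
# Nearest-taxon semantics allow self-match: a taxon present in both
# communities contributes distance 0, so bMNTD(A, A) = 0.
.bmntd_pair <- function(wa, wb, ia, ib, D) {
  M <- D[ia, ib, drop = FALSE]
  min_a <- M[cbind(seq_along(ia), max.col(-M, ties.method = "first"))]
  Mt <- t.default(M)
  min_b <- Mt[cbind(seq_along(ib), max.col(-Mt, ties.method = "first"))]
  0.5 * (sum(wa * min_a) + sum(wb * min_b))
}

# Precompute, per sample, the index set of taxa present and their weights.
# dist_index maps table taxon order -> patristic matrix row order.
.bmntd_prepare <- function(table, dist, abundance_weighted) {
  table <- as_otu_table(table)
  counts <- .otu_counts(table)
  present <- colSums(counts) > 0
  missing <- setdiff(colnames(counts)[present], rownames(dist))
  if (length(missing))
    stop(sprintf("%d taxa with nonzero abundance absent from the distance matrix (e.g. '%s')",
                 length(missing), missing[1]))
  dist_index <- match(colnames(counts), rownames(dist))
  f <- relative_abundances(table)
  samples <- rownames(counts)
  idx <- vector("list", length(samples))
  wts <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    nz <- which(counts[i, ] > 0)
    if (!length(nz)) stop(sprintf("sample '%s' has no taxa", samples[i]))
    idx[[i]] <- dist_index[nz]
    wts[[i]] <- if (abundance_weighted) f[i, nz] else rep(1 / length(nz), length(nz))
  }
  list(samples = samples, idx = idx, wts = wts)
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For communities A and B with relative abundances f and patristic distances
#' d, \deqn{\beta MNTD(A,B) = \frac12\Big[\sum_{i \in A} f_i \min_{j \in B}
#' d_{ij} + \sum_{j \in B} f_j \min_{i \in A} d_{ij}\Big]} where the minima
#' run over taxa with nonzero abundance in the opposite community and a taxon
#' shared by both communities matches itself at distance zero.  The
#' unweighted variant replaces f by 1/richness.
#'
#' @param table an [otu_table]; all taxa with nonzero abundance must appear
#'   in \code{dist}.
#' @param dist patristic distance matrix from [cophenetic_distances()].
#' @param abundance_weighted weight taxa by relative abundance (the pipeline
#'   default) or equally.
#' @return symmetric numeric matrix of betaMNTD values with sample ids as
#'   dimnames.
#' @references Webb, C.O. et al. (2008) Phylocom; Stegen, J.C. et al. (2013)
#'   ISME J 7:2069-2079 (quantitative process framework).
#' @export
beta_mntd <- function(table, dist, abundance_weighted = TRUE) {
  prep <- .bmntd_prepare(table, dist, abundance_weighted)
  n <- length(prep$samples)
  if (n < 2) stop("betaMNTD needs at least 2 samples")
  out <- matrix(0, n, n, dimnames = list(prep$samples, prep$samples))
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      v <- .bmntd_pair(prep$wts[[a]], prep$wts[[b]], prep$idx[[a]], prep$idx[[b]], dist)
      out[a, b] <- out[b, a] <- v
    }
  }
  out
}
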