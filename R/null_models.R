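#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \code{BC = sum |x_i - y_i| / sum (x_i + y_i)}; 0 for identical vectors, 1
#' for disjoint supports.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return a number in \code{[0, 1]}.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

# normalize a pairs specification to a two-column character matrix of ids
.resolve_pairs <- function(table, pairs) {
  ids <- rownames(table)
  if (is.null(pairs)) {
    if (length(ids) < 2) stop("need at least 2 samples")
    cmb <- utils::combn(ids, 2)
    pairs <- cbind(cmb[1, ], cmb[2, ])
  } else {
    if (is.data.frame(pairs)) {
      pairs <- cbind(as.character(pairs$sample_a), as.character(pairs$sample_b))
    } else {
      pairs <- cbind(as.character(pairs[, 1]), as.character(pairs[, 2]))
    }
  }
  unknown <- setdiff(c(pairs), ids)
  if (length(unknown))
    stop(sprintf("pair references unknown sample '%s'", unknown[1]))
  pairs
}

#' Beta nearest taxon index (betaNTI) via a tip-shuffle null
#'
#' Each null iteration permutes taxon identities across the tips of the
#' phylogeny (one permutation of the full taxa pool per iteration, shared by
#' every sample pair in that iteration) and recomputes betaMNTD for every
#' pair.  \code{betaNTI = (betaMNTD_obs - mean_null) / sd_null}.  Values with
#' \code{|betaNTI| > 2} indicate selection.  Pairs whose null distribution is
#' degenerate (sd 0) get \code{NA} with a warning and should be forwarded to
#' the Raup-Crick stage.
#'
#' @param table an [otu_table].
#' @param dist patristic distance matrix ([cophenetic_distances()]).
#' @param n_iter number of null iterations (default 999, the convention of
#'   the null-model framework).
#' @param seed master seed; results are reproducible bit-for-bit.
#' @param pairs optional restriction: a two-column matrix/data.frame of
#'   sample-id pairs (columns \code{sample_a}, \code{sample_b}); default all
#'   pairs.
#' @param abundance_weighted weight taxa by relative abundance.
#' @param per_pair_shuffle draw an independent permutation per pair and
#'   iteration (seeded per pair) instead of one shared permutation per
#'   iteration.
#' @return data.frame with one row per pair: \code{sample_a}, \code{sample_b},
#'   \code{bmntd_obs}, \code{null_mean}, \code{null_sd}, \code{bnti}; the
#'   attributes \code{n_iter} and \code{seed} record the run.
#' @export
beta_nti <- function(table, dist, n_iter = 999, seed = 1L, pairs = NULL,
                     abundance_weighted = TRUE, per_pair_shuffle = FALSE) {
  if (n_iter < 2) stop("n_iter must be at least 2")
  table <- as_otu_table(table)
  pairs <- .resolve_pairs(table, pairs)
  prep <- .bmntd_prepare(table, dist, abundance_weighted)
  np <- nrow(pairs)
  ai <- match(pairs[, 1], prep$samples)
  bi <- match(pairs[, 2], prep$samples)
  ntaxa <- nrow(dist)

  obs <- numeric(np)
  for (p in seq_len(np))
    obs[p] <- .bmntd_pair(prep$wts[[ai[p]]], prep$wts[[bi[p]]],
                          prep$idx[[ai[p]]], prep$idx[[bi[p]]], dist)

  nulls <- matrix(NA_real_, n_iter, np)
  if (per_pair_shuffle) {
    for (p in seq_len(np)) {
      key <- sort(c(pairs[p, 1], pairs[p, 2]))
      set.seed(derive_seed(seed, "bnti_pair", key[1], key[2]))
      for (r in seq_len(n_iter)) {
        perm <- sample.int(ntaxa)
        nulls[r, p] <- .bmntd_pair(prep$wts[[ai[p]]], prep$wts[[bi[p]]],
                                   perm[prep$idx[[ai[p]]]], perm[prep$idx[[bi[p]]]], dist)
      }
    }
  } else {
    set.seed(derive_seed(seed, "bnti"))
    for (r in seq_len(n_iter)) {
      perm <- sample.int(ntaxa)
      for (p in seq_len(np))
        nulls[r, p] <- .bmntd_pair(prep$wts[[ai[p]]], prep$wts[[bi[p]]],
                                   perm[prep$idx[[ai[p]]]], perm[prep$idx[[bi[p]]]], dist)
    }
  }

  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, stats::sd)
  bnti <- (obs - null_mean) / null_sd
  degenerate <- null_sd == 0
  if (any(degenerate)) {
    warning(sprintf("%d pair(s) have a degenerate null (sd = 0); betaNTI set to NA",
                    sum(degenerate)))
    bnti[degenerate] <- NA_real_
  }
  out <- data.frame(sample_a = pairs[, 1], sample_b = pairs[, 2],
                    bmntd_obs = obs, null_mean = null_mean,
                    null_sd = null_sd, bnti = bnti,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_iter") <- n_iter
  attr(out, "seed") <- seed
  out
}

# assemble one null community: preserve richness and total abundance.
# Membership: `richness` taxa drawn without replacement with probability
# proportional to occupancy; each drawn taxon seeds 1 individual; the
# remaining J - richness individuals are multinomial with probability
# proportional to metacommunity relative abundance of the drawn taxa.
.rc_null_sample <- function(richness, J, occ, ab) {
  n <- length(occ)
  if (richness > sum(occ > 0))
    stop("sample richness exceeds metacommunity richness")  # guarded; cannot occur
  taxa <- sample.int(n, richness, prob = occ)
  x <- numeric(n)
  x[taxa] <- 1
  if (J > richness) {
    x[taxa] <- x[taxa] + rmultinom(1, J - richness, ab[taxa])[, 1]
  }
  x
}

#' Abundance-based Raup-Crick index with Bray-Curtis (RC-bray)
#'
#' For each pair, every null iteration reassembles both samples from the
#' metacommunity (the full table handed in), preserving each sample's
#' observed richness and total abundance, and computes the null Bray-Curtis
#' dissimilarity.  With \code{alpha = [#(BC_null < BC_obs) + 0.5 #(BC_null =
#' BC_obs)] / n_iter}, \code{RC = 2 alpha - 1}, scaled to \code{[-1, 1]}.
#' \code{RC < -0.95} indicates homogenizing dispersal, \code{RC > 0.95}
#' dispersal limitation, and intermediate values drift.
#'
#' Equality of null and observed Bray-Curtis uses a 1e-12 tolerance to avoid
#' floating-point false ties.  Each pair runs in its own random stream
#' derived from the master seed and the (sorted) sample ids, so results do
#' not depend on pair evaluation order.
#'
#' @param table an [otu_table] of integer counts; all its samples define the
#'   metacommunity used for occupancy and abundance weights.
#' @param pairs pairs to evaluate (as in [beta_nti()]); default all pairs.
#' @param n_iter number of null iterations (default 999).
#' @param seed master seed.
#' @return data.frame with \code{sample_a}, \code{sample_b}, \code{bc_obs},
#'   \code{rc_bray}; attributes \code{n_iter}, \code{seed}.
#' @references Chase, J.M. et al. (2011) Ecosphere 2:art24; Stegen, J.C. et
#'   al. (2013) ISME J 7:2069-2079 (abundance-based modification).
#' @export
raup_crick_bray <- function(table, pairs = NULL, n_iter = 999, seed = 1L) {
  if (n_iter < 2) stop("n_iter must be at least 2")
  table <- as_otu_table(table)
  counts <- .otu_counts(table)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("RC-bray requires integer counts (the null model reassembles individuals)")
  counts <- round(counts)
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop(sprintf("sample '%s' has zero total abundance", rownames(counts)[totals == 0][1]))
  pairs <- .resolve_pairs(table, pairs)
  occ <- colSums(counts > 0)
  ab <- colSums(counts)
  ab <- ab / sum(ab)
  rich <- rowSums(counts > 0)

  np <- nrow(pairs)
  bc_obs <- numeric(np)
  rc <- numeric(np)
  for (p in seq_len(np)) {
    # canonical (sorted) order: RC(a, b) must equal RC(b, a) bit-for-bit
    key <- sort(c(pairs[p, 1], pairs[p, 2]))
    a <- key[1]; b <- key[2]
    xa <- counts[a, ]; xb <- counts[b, ]
    bc0 <- bray_curtis(xa, xb)
    set.seed(derive_seed(seed, "rc", key[1], key[2]))
    bc_null <- numeric(n_iter)
    for (r in seq_len(n_iter)) {
      na_ <- .rc_null_sample(rich[a], totals[a], occ, ab)
      nb_ <- .rc_null_sample(rich[b], totals[b], occ, ab)
      bc_null[r] <- bray_curtis(na_, nb_)
    }
    tie <- abs(bc_null - bc0) <= 1e-12
    less <- (bc_null < bc0) & !tie
    alpha <- (sum(less) + 0.5 * sum(tie)) / n_iter
    bc_obs[p] <- bc0
    rc[p] <- 2 * alpha - 1
  }
  out <- data.frame(sample_a = pairs[, 1], sample_b = pairs[, 2],
                    bc_obs = bc_obs, rc_bray = rc,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_iter") <- n_iter
  attr(out, "seed") <- seed
  out
}
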