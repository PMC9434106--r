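# Independent reference implementations, used only to check package code.
# They deliberately share no code path with the implementations under test.

# betaMNTD by explicit double loop over taxa pairs
oracle_bmntd <- function(counts, D, weighted = TRUE) {
  f <- sweep(counts, 1, rowSums(counts), "/")
  tid <- colnames(counts)
  pair_val <- function(a, b) {
    ia <- which(counts[a, ] > 0)
    ib <- which(counts[b, ] > 0)
    da <- 0
    for (i in ia) {
      best <- Inf
      for (j in ib) best <- min(best, D[tid[i], tid[j]])
      w <- if (weighted) f[a, i] else 1 / length(ia)
      da <- da + w * best
    }
    db <- 0
    for (j in ib) {
      best <- Inf
      for (i in ia) best <- min(best, D[tid[j], tid[i]])
      w <- if (weighted) f[b, j] else 1 / length(ib)
      db <- db + w * best
    }
    0.5 * (da + db)
  }
  n <- nrow(counts)
  out <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n))
    out[a, b] <- out[b, a] <- pair_val(a, b)
  out
}

# patristic distances by walking every tip's path to the root
oracle_cophenetic <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  plen <- numeric(nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_to_root <- function(v) {
    nodes <- v
    while (v != root) {
      v <- parent[v]
      nodes <- c(nodes, v)
    }
    nodes
  }
  dist_up <- function(v) {
    d <- 0
    while (v != root) {
      d <- d + plen[v]
      v <- parent[v]
    }
    d
  }
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) {
    for (j in seq(i + 1, ntip)) {
      pi_ <- path_to_root(i)
      pj_ <- path_to_root(j)
      mrca <- pi_[pi_ %in% pj_][1]
      D[i, j] <- D[j, i] <- dist_up(i) + dist_up(j) - 2 * dist_up(mrca)
    }
  }
  D
}

# pseudo-F from Anderson's partition of squared distances
oracle_permanova_f <- function(d, grouping) {
  d <- as.matrix(d)
  n <- nrow(d)
  g <- as.factor(grouping)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  a <- nlevels(g)
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# random fixture table with no empty sample
random_table <- function(n_samples, n_taxa, seed, lambda = 3) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples)
  for (i in seq_len(n_samples))
    if (sum(m[i, ]) == 0) m[i, sample.int(n_taxa, 1)] <- 1
  otu_table(m, paste0("s", seq_len(n_samples)), paste0("t", seq_len(n_taxa)))
}
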