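test_that("Bray-Curtis matches hand values and bounds", {
  expect_equal(bray_curtis(c(1, 1), c(0, 2)), 0.5)
  expect_equal(bray_curtis(c(3, 2, 5), c(3, 2, 5)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 4)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(-1, 2), c(1, 1)), "non-negative")
  for (seed in 1:5) {
    set.seed(seed)
    x <- rpois(8, 3); y <- rpois(8, 3)
    if (sum(x) + sum(y) == 0) next
    bc <- bray_curtis(x, y)
    expect_gte(bc, 0); expect_lte(bc, 1)
    expect_equal(bc, bray_curtis(y, x))
  }
})

test_that("betaNTI is reproducible, relabeling-invariant, and flags degenerate nulls", {
  phy <- simulate_tree(20, seed = 5)
  D <- cophenetic_distances(phy)
  tab <- random_table(4, 20, seed = 6, lambda = 2)
  colnames(tab) <- phy$tip.label

  a <- beta_nti(tab, D, n_iter = 49, seed = 11)
  b <- beta_nti(tab, D, n_iter = 49, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$bnti, beta_nti(tab, D, n_iter = 49, seed = 12)$bnti))

  # relabeling samples permutes rows but not values
  swap <- otu_table(unclass(tab)[c(3, 1, 4, 2), ])
  s <- beta_nti(swap, D, n_iter = 49, seed = 11)
  key_a <- paste(pmin(a$sample_a, a$sample_b), pmax(a$sample_a, a$sample_b))
  key_s <- paste(pmin(s$sample_a, s$sample_b), pmax(s$sample_a, s$sample_b))
  expect_equal(s$bnti[match(key_a, key_s)], a$bnti)

  # both communities carry only one (shared) taxon -> null sd is 0
  degen <- otu_table(rbind(u = c(5, 0, 0), v = c(3, 0, 0)),
                     taxon_ids = phy$tip.label[1:3])
  expect_warning(dn <- beta_nti(degen, D, n_iter = 19, seed = 1), "degenerate null")
  expect_true(is.na(dn$bnti))

  # per-pair shuffling is a different but valid null
  pp <- beta_nti(tab, D, n_iter = 49, seed = 11, per_pair_shuffle = TRUE)
  expect_equal(pp$bmntd_obs, a$bmntd_obs)
  expect_false(identical(pp$bnti, a$bnti))
})

test_that("RC-bray hits its analytic endpoints", {
  # identical pair inside a heterogeneous metacommunity: BC_obs = 0 is below
  # every non-degenerate null draw, so RC = -1
  sc <- generate_scenario(scenario_spec("drift", seed = 3))
  counts <- unclass(sc$table)
  counts["B", ] <- counts["A", ]
  tab <- otu_table(counts)
  rc <- raup_crick_bray(tab, pairs = cbind("A", "B"), n_iter = 99, seed = 4)
  expect_equal(rc$bc_obs, 0)
  expect_equal(rc$rc_bray, -1)

  # single-taxon metacommunity: every null equals the observed pair -> all
  # ties -> alpha = 0.5 -> RC = 0
  one <- otu_table(rbind(a = 5, b = 7), taxon_ids = "t1")
  rc0 <- raup_crick_bray(one, n_iter = 49, seed = 1)
  expect_equal(rc0$rc_bray, 0)
})

test_that("RC-bray stays in [-1, 1] and is order-independent and reproducible", {
  for (seed in 1:4) {
    tab <- random_table(4, 12, seed = 400 + seed, lambda = 2)
    rc <- raup_crick_bray(tab, n_iter = 29, seed = seed)
    expect_true(all(rc$rc_bray >= -1 & rc$rc_bray <= 1))
  }
  tab <- random_table(3, 10, seed = 77, lambda = 2)
  fwd <- raup_crick_bray(tab, pairs = rbind(c("s1", "s2"), c("s2", "s3")),
                         n_iter = 59, seed = 5)
  bwd <- raup_crick_bray(tab, pairs = rbind(c("s3", "s2"), c("s2", "s1")),
                         n_iter = 59, seed = 5)
  expect_equal(fwd$rc_bray, rev(bwd$rc_bray))
  again <- raup_crick_bray(tab, pairs = rbind(c("s1", "s2"), c("s2", "s3")),
                           n_iter = 59, seed = 5)
  expect_identical(fwd, again)
})

test_that("null communities preserve richness and total abundance", {
  tab <- random_table(5, 15, seed = 21, lambda = 2)
  counts <- round(unclass(tab))
  occ <- colSums(counts > 0)
  ab <- colSums(counts); ab <- ab / sum(ab)
  set.seed(99)
  for (i in seq_len(nrow(counts))) {
    rich <- sum(counts[i, ] > 0)
    J <- sum(counts[i, ])
    for (r in 1:20) {
      x <- phylocascade:::.rc_null_sample(rich, J, occ, ab)
      expect_equal(sum(x > 0), rich)
      expect_equal(sum(x), J)
      expect_true(all(x[occ == 0] == 0))
    }
  }
})

test_that("RC-bray refuses non-integer abundance tables", {
  tab <- otu_table(rbind(a = c(1.5, 2), b = c(2, 3)))
  expect_error(raup_crick_bray(tab, n_iter = 9), "integer counts")
})
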