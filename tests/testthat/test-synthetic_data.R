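test_that("Yule trees have the right shape and mean depth", {
  cherry <- simulate_tree(2, seed = 1)
  expect_equal(length(cherry$tip.label), 2)
  expect_equal(cherry$Nnode, 1)

  for (seed in 1:3) {
    phy <- simulate_tree(25, seed = seed)
    expect_equal(length(phy$tip.label), 25)
    expect_false(anyDuplicated(phy$tip.label) > 0)
    expect_true(all(phy$edge.length > 0))
    expect_true(ape::is.ultrametric(phy, tol = 1e-8))
    expect_true(ape::is.rooted(phy))
  }
  expect_identical(ape::write.tree(simulate_tree(10, seed = 4)),
                   ape::write.tree(simulate_tree(10, seed = 4)))
  expect_error(simulate_tree(1), "at least 2")

  # E[tip depth] for a Yule process started at 2 lineages, run to n tips and
  # stretched by one further waiting time, is sum_{k=2}^{n} 1/(k * lambda)
  n <- 8
  depths <- vapply(1:400, function(s) {
    phy <- simulate_tree(n, seed = 10000 + s)
    max(ape::node.depth.edgelength(phy))
  }, numeric(1))
  expected <- sum(1 / (2:n))
  se <- stats::sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("Brownian traits follow the BM variance and covariance laws", {
  phy <- simulate_tree(6, seed = 77)
  expect_equal(unname(evolve_trait(phy, sigma2 = 0, root_value = 1.5, seed = 1)),
               rep(1.5, 6))

  sigma2 <- 0.6
  reps <- 800
  X <- vapply(seq_len(reps), function(s)
    evolve_trait(phy, sigma2 = sigma2, root_value = 0, seed = s),
    numeric(6))
  depth <- max(ape::node.depth.edgelength(phy))  # ultrametric: same for all tips
  D <- cophenetic_distances(phy)

  v <- apply(X, 1, stats::var)
  se_v <- v * sqrt(2 / (reps - 1))
  expect_true(all(abs(v - sigma2 * depth) < 3.5 * se_v))

  # Cov(tip_i, tip_j) = sigma2 * shared path = sigma2 * (depth - d_ij / 2)
  C <- stats::cov(t(X))
  for (i in 1:5) for (j in (i + 1):6) {
    shared <- depth - D[rownames(C)[i], colnames(C)[j]] / 2
    se_c <- sqrt((v[i] * v[j] + C[i, j]^2) / reps)
    expect_lt(abs(C[i, j] - sigma2 * shared), 4 * se_c + 1e-9)
  }
})

test_that("community assembly respects the filter and conserves size", {
  pool <- c(0.5, 0.3, 0.2)
  traits <- c(-1, 0, 1)
  x <- assemble_community(pool, traits, env = 0, sigma = Inf, J = 500, seed = 1)
  expect_equal(sum(x), 500)

  # flat filter: expected proportions equal pool proportions
  reps <- vapply(1:400, function(s)
    assemble_community(pool, traits, 0, Inf, 100, seed = s)[1], numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 50), 3 * se)

  # vanishing filter width: all mass on the taxon nearest the optimum
  tight <- assemble_community(pool, traits, env = 0.9, sigma = 0, J = 200, seed = 2)
  expect_equal(unname(tight), c(0, 0, 200))

  expect_equal(assemble_community(pool, traits, 0, 1, 300, seed = 9),
               assemble_community(pool, traits, 0, 1, 300, seed = 9))
  expect_error(assemble_community(c(0.6, 0.6), traits[1:2], 0, 1, 10), "sum to 1")
  expect_error(assemble_community(pool, traits, 0, 1, 0), "at least 1")
  expect_error(assemble_community(pool, traits[1:2], 0, 1, 10), "differ in length")
})

test_that("scenario generation is valid, seed-stable, and encodes its truth", {
  for (proc in c("selection", "homogenizing_dispersal", "dispersal_limitation", "drift")) {
    sc <- generate_scenario(scenario_spec(proc, n_taxa = 40, J = 400, seed = 2))
    expect_s3_class(sc$table, "otu_table")
    expect_true(all(colnames(sc$table) %in% sc$tree$tip.label))
    expect_equal(sc$focal_pair, c("A", "B"))
    expect_equal(nrow(sc$table), 2 + sc$spec$n_context)
    expect_equal(sc$truth,
                 c(selection = "S", homogenizing_dispersal = "HD",
                   dispersal_limitation = "DL", drift = "D")[[proc]])
    sc2 <- generate_scenario(scenario_spec(proc, n_taxa = 40, J = 400, seed = 2))
    expect_identical(unclass(sc$table), unclass(sc2$table))
  }
  # a selection pair with zero environmental offset is drift-like: the two
  # communities share one filtered pool and correlate strongly
  sc0 <- generate_scenario(scenario_spec("selection", env_offset = 0, seed = 3))
  expect_gt(stats::cor(unclass(sc0$table)["A", ], unclass(sc0$table)["B", ]), 0.9)

  expect_error(scenario_spec("selection", filter_width = Inf), "finite filter width")
  expect_error(scenario_spec("drift", n_taxa = 3), "at least 4")
  expect_error(scenario_spec("drift", pool_overlap = 1.5), "in \\[0, 1\\]")
})

test_that("the synthetic cascade reproduces the sampling design", {
  cs <- generate_cascade_study(seed = 5, n_taxa = 60, J = 400)
  expect_equal(nrow(cs$table), 24)               # 4 reservoirs x 6 events
  expect_equal(nrow(cs$metadata), 24)
  expect_setequal(unique(cs$metadata$reservoir), c("BB", "Pr", "NA", "TI"))
  expect_setequal(unique(cs$metadata$event), c("D1", "D2", "D3", "R1", "R2", "R3"))

  # trophic gradient decreases monotonically along the cascade in every event
  for (ev in unique(cs$metadata$event)) {
    ids <- paste(c("BB", "Pr", "NA", "TI"), ev, sep = "_")
    expect_true(all(diff(cs$env[ids, "trophic_index"]) < 0))
  }

  cs2 <- generate_cascade_study(seed = 5, n_taxa = 60, J = 400)
  expect_identical(unclass(cs$table), unclass(cs2$table))
  expect_equal(cs$env, cs2$env)

  # emitted files round-trip through the io layer
  dir <- file.path(tempdir(), "cascade_rt")
  write_synthetic_dataset(cs, dir)
  back <- read_otu_table(file.path(dir, "otu_table.tsv"))
  expect_equal(unclass(back), unclass(cs$table), ignore_attr = TRUE)
  tr <- read_tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, cs$tree$tip.label)
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$sample_id, cs$metadata$sample_id)
  expect_equal(md$reservoir, cs$metadata$reservoir)  # "NA" survives the trip
  env <- read_env_table(file.path(dir, "env.tsv"))
  expect_equal(env, cs$env, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
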