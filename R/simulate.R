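#' Simulate a pure-birth (Yule) phylogeny
#'
#' Forward simulation with exponential waiting times: while k lineages are
#' alive the time to the next speciation is Exp(k * birth_rate) and a
#' uniformly chosen lineage splits.  After the n-th tip appears the tree is
#' extended by one final exponential waiting time, so the result is
#' ultrametric with all tips at the present.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed; the simulation is deterministic given it.
#' @param birth_rate speciation rate (per lineage per unit time).
#' @return an \code{ape::phylo} with tip labels \code{t1..tn}.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, birth_rate = 1) {
  if (n_taxa < 2) stop("n_taxa must be at least 2")
  set.seed(derive_seed(seed, "yule"))
  n <- as.integer(n_taxa)
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  root <- n + 1L
  next_internal <- n + 2L
  active_parent <- c(root, root)
  active_len <- c(0, 0)
  k <- 2L
  while (k < n) {
    active_len <- active_len + rexp(1, birth_rate * k)
    i <- sample.int(k, 1)
    nd <- next_internal; next_internal <- next_internal + 1L
    parent <- c(parent, active_parent[i]); child <- c(child, nd)
    elen <- c(elen, active_len[i])
    active_parent[i] <- nd; active_len[i] <- 0
    active_parent <- c(active_parent, nd); active_len <- c(active_len, 0)
    k <- k + 1L
  }
  active_len <- active_len + rexp(1, birth_rate * k)   # stretch to the present
  parent <- c(parent, active_parent)
  child <- c(child, seq_len(k))
  elen <- c(elen, active_len)
  phy <- list(edge = cbind(parent, child), edge.length = elen,
              tip.label = paste0("t", seq_len(n)), Nnode = n - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' Evolve a continuous trait by Brownian motion along a tree
#'
#' Child value = parent value + Normal(0, sigma2 * branch_length).  This is
#' the minimal mechanism producing phylogenetically conserved niche traits:
#' closely related tips end up with similar habitat optima, the assumption
#' licensing betaMNTD-based inference.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @param sigma2 Brownian rate (trait variance per unit branch length).
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
evolve_trait <- function(tree, sigma2 = 1, root_value = 0, seed = 1L) {
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  set.seed(derive_seed(seed, "bm"))
  x <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2),
                       root.value = root_value)
  x[tree$tip.label]
}

#' Assemble a local community by filtered multinomial sampling
#'
#' Draws J individuals with probability proportional to \code{pool_i *
#' exp(-(trait_i - env)^2 / (2 sigma^2))}: a Gaussian environmental filter of
#' width \code{sigma} centered on the local optimum \code{env}, acting on a
#' regional species pool.  \code{sigma = Inf} disables filtering (neutral
#' draw); \code{sigma = 0} concentrates the community on the taxa whose
#' trait is closest to \code{env}.
#'
#' @param pool regional relative abundances (sums to 1).
#' @param traits per-taxon niche trait values, aligned with \code{pool}.
#' @param env local environmental optimum (trait units).
#' @param sigma filter width (trait units, > 0 or Inf or 0).
#' @param J community size (individuals).
#' @param seed integer seed.
#' @return integer abundance vector summing to J (named like \code{pool}).
#' @export
assemble_community <- function(pool, traits, env, sigma, J, seed = 1L) {
  if (length(pool) != length(traits)) stop("pool and traits differ in length")
  if (J < 1) stop("J must be at least 1")
  if (abs(sum(pool) - 1) > 1e-8) stop("pool must sum to 1")
  if (all(pool == 0)) stop("pool is empty")
  if (sigma < 0) stop("sigma must be non-negative")
  d2 <- (traits - env)^2
  if (sigma == 0) {
    m <- min(d2[pool > 0])
    w <- pool * as.numeric(d2 == m)
  } else if (is.infinite(sigma)) {
    w <- pool
  } else {
    m <- min(d2[pool > 0])      # rescale so the best taxon has weight ~pool
    w <- pool * exp(-(d2 - m) / (2 * sigma^2))
  }
  if (all(w == 0)) stop("all filter weights are zero")
  set.seed(derive_seed(seed, "assemble"))
  x <- rmultinom(1, J, w)[, 1]
  names(x) <- names(pool)
  x
}

# Lognormal rank-abundance pool over a support set.  The heavy tail
# (sdlog = 2) matters: it keeps per-sample richness well below the
# metacommunity richness, which is what lets the Raup-Crick null distinguish
# draws that share membership from null reassemblies that do not.
.lognormal_pool <- function(n_taxa, support = seq_len(n_taxa), meanlog = 0, sdlog = 2) {
  p <- numeric(n_taxa)
  p[support] <- rlnorm(length(support), meanlog, sdlog)
  p / sum(p)
}

#' Specify a synthetic assembly scenario
#'
#' Bundles the parameters of one two-sample scenario with a known
#' ground-truth process.  The strong-effect defaults were fixed once by the
#' end-to-end recovery experiment shipped with the package tests and are not
#' tuned per run.
#'
#' @param process one of \code{"selection"}, \code{"homogenizing_dispersal"},
#'   \code{"dispersal_limitation"}, \code{"drift"}.
#' @param n_taxa tree size (>= 4).
#' @param J community size in individuals; defaults to 2000, and to 4000 for
#'   homogenizing dispersal (a large draw keeps sampling noise well below
#'   the null model's own assembly noise without saturating richness).
#' @param filter_width Gaussian filter width sigma (trait units); only
#'   selection filters, the other processes use \code{Inf}.
#' @param env_offset trait-space separation Delta of the two selective
#'   environments.
#' @param pool_overlap fraction of shared support between the two source
#'   pools under dispersal limitation.
#' @param n_context number of additional unfiltered metacommunity samples
#'   emitted alongside the focal pair.  The Raup-Crick null draws its
#'   occupancy and abundance weights from the whole table, so these context
#'   samples supply the metacommunity-level heterogeneity against which the
#'   focal pair is judged (as the real analysis judges a reservoir pair
#'   against the full season's table).
#' @param pool_noise lognormal sd of the per-taxon perturbation applied to
#'   the regional pool for every context sample: each local pool is
#'   \code{pool * exp(N(0, pool_noise^2))}, renormalized — a
#'   demographic-drift realization of the metacommunity.
#' @param drift_noise perturbation sd for the two focal pools of a drift
#'   scenario; smaller than \code{pool_noise} so the focal pair's
#'   dissimilarity sits inside the null distribution rather than beyond it.
#' @param seed master seed.
#' @return list of class \code{scenario_spec}.
#' @export
scenario_spec <- function(process = c("selection", "homogenizing_dispersal",
                                      "dispersal_limitation", "drift"),
                          n_taxa = 200,
                          J = if (process == "homogenizing_dispersal") 4000 else 2000,
                          filter_width = if (process == "selection") 0.5 else Inf,
                          env_offset = 4, pool_overlap = 0.1,
                          n_context = 4, pool_noise = 1, drift_noise = 0.25,
                          seed = 1L) {
  process <- match.arg(process)
  if (n_taxa < 4) stop("n_taxa must be at least 4")
  if (J < 1) stop("J must be at least 1")
  if (filter_width <= 0) stop("filter_width must be positive (or Inf)")
  if (process == "selection" && is.infinite(filter_width))
    stop("a selection scenario needs a finite filter width")
  if (pool_overlap < 0 || pool_overlap > 1) stop("pool_overlap must be in [0, 1]")
  if (n_context < 0) stop("n_context must be non-negative")
  if (pool_noise < 0 || drift_noise < 0) stop("pool perturbation sds must be non-negative")
  structure(list(process = process, n_taxa = as.integer(n_taxa), J = as.integer(J),
                 filter_width = filter_width, env_offset = env_offset,
                 pool_overlap = pool_overlap, n_context = as.integer(n_context),
                 pool_noise = pool_noise, drift_noise = drift_noise,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# local pool = regional pool under one realization of demographic drift
.perturbed_pool <- function(pool, pool_noise) {
  w <- pool * exp(rnorm(length(pool), 0, pool_noise))
  w / sum(w)
}

#' Generate a focal community pair under a known assembly process
#'
#' Builds a Yule tree, Brownian niche traits and a heavy-tailed lognormal
#' regional pool, then assembles a focal pair of communities (samples
#' \code{A}, \code{B}) plus \code{n_context} unfiltered metacommunity
#' samples (drawn from independently perturbed copies of the pool) that give
#' the Raup-Crick null its metacommunity-level heterogeneity:
#' \describe{
#'   \item{selection}{Gaussian filters of width sigma centered at
#'     \code{env - Delta/2} and \code{env + Delta/2} act on the conserved
#'     traits; expected \code{|betaNTI| > 2}.}
#'   \item{homogenizing_dispersal}{two large draws from one identical pool
#'     (unlimited organism exchange), no filtering; expected
#'     \code{RC -> -1}.}
#'   \item{dispersal_limitation}{draws from partially disjoint,
#'     phylogenetically random pools (support overlap \code{pool_overlap});
#'     expected \code{RC -> +1} with betaNTI near zero.}
#'   \item{drift}{independent draws from two weakly perturbed copies of the
#'     pool (perturbation sd \code{drift_noise}) — each a demographic-drift
#'     realization of the same metacommunity; expected \code{|RC| < 0.95}
#'     and betaNTI near zero.}
#' }
#'
#' @param spec a [scenario_spec()].
#' @return list of class \code{synthetic_dataset}: \code{tree},
#'   \code{traits}, \code{table} ([otu_table] whose first two rows are the
#'   focal pair), \code{metadata} (with a \code{role} column:
#'   \code{focal}/\code{context}), \code{focal_pair} (c("A", "B")),
#'   \code{truth} (the generating process label as used by
#'   [classify_pair()]: S, HD, DL or D), \code{spec}.
#' @export
generate_scenario <- function(spec) {
  if (!inherits(spec, "scenario_spec")) spec <- do.call(scenario_spec, as.list(spec))
  n <- spec$n_taxa
  tree <- simulate_tree(n, derive_seed(spec$seed, "tree"))
  traits <- evolve_trait(tree, sigma2 = 1, root_value = 0,
                         seed = derive_seed(spec$seed, "trait"))
  set.seed(derive_seed(spec$seed, "pool"))
  pool <- .lognormal_pool(n)
  names(pool) <- tree$tip.label

  sa <- derive_seed(spec$seed, "comm", "A")
  sb <- derive_seed(spec$seed, "comm", "B")
  if (spec$process == "selection") {
    center <- stats::median(traits)
    xa <- assemble_community(pool, traits, center - spec$env_offset / 2,
                             spec$filter_width, spec$J, sa)
    xb <- assemble_community(pool, traits, center + spec$env_offset / 2,
                             spec$filter_width, spec$J, sb)
    truth <- "S"
  } else if (spec$process == "homogenizing_dispersal") {
    xa <- assemble_community(pool, traits, 0, Inf, spec$J, sa)
    xb <- assemble_community(pool, traits, 0, Inf, spec$J, sb)
    truth <- "HD"
  } else if (spec$process == "dispersal_limitation") {
    half <- floor(n / 2)
    n_shared <- round(spec$pool_overlap * half)
    set.seed(derive_seed(spec$seed, "pools"))
    shared <- sample.int(n, n_shared)
    rest <- sample(setdiff(seq_len(n), shared))
    own_a <- rest[seq_len(half - n_shared)]
    own_b <- rest[half - n_shared + seq_len(half - n_shared)]
    pool_a <- .lognormal_pool(n, support = c(shared, own_a))
    pool_b <- .lognormal_pool(n, support = c(shared, own_b))
    names(pool_a) <- names(pool_b) <- tree$tip.label
    xa <- assemble_community(pool_a, traits, 0, Inf, spec$J, sa)
    xb <- assemble_community(pool_b, traits, 0, Inf, spec$J, sb)
    truth <- "DL"
  } else {
    set.seed(derive_seed(spec$seed, "drift_pools"))
    pool_a <- .perturbed_pool(pool, spec$drift_noise)
    pool_b <- .perturbed_pool(pool, spec$drift_noise)
    xa <- assemble_community(pool_a, traits, 0, Inf, spec$J, sa)
    xb <- assemble_community(pool_b, traits, 0, Inf, spec$J, sb)
    truth <- "D"
  }
  counts <- rbind(A = xa, B = xb)
  ids <- c("A", "B")
  if (spec$n_context > 0) {
    for (i in seq_len(spec$n_context)) {
      set.seed(derive_seed(spec$seed, "ctx_pool", i))
      pool_i <- .perturbed_pool(pool, spec$pool_noise)
      counts <- rbind(counts, assemble_community(pool_i, traits, 0, Inf, spec$J,
                                                 derive_seed(spec$seed, "ctx", i)))
      ids <- c(ids, paste0("C", i))
    }
  }
  rownames(counts) <- ids
  table <- otu_table(counts, taxon_ids = tree$tip.label)
  metadata <- data.frame(sample_id = ids,
                         reservoir = c("BB", "Pr", rep("ctx", spec$n_context)),
                         event = "D1", season = "dry",
                         role = c("focal", "focal", rep("context", spec$n_context)),
                         stringsAsFactors = FALSE)
  structure(list(tree = tree, traits = traits, table = table,
                 metadata = metadata, focal_pair = c("A", "B"),
                 truth = truth, spec = spec),
            class = "synthetic_dataset")
}

#' Generate a full synthetic cascade study
#'
#' Emulates the sampled design: 4 reservoirs (BB, Pr, NA, TI) x 6 events
#' (D1-D3 dry, R1-R3 rainy) x 1 subcommunity, 24 samples in all.  A trophic
#' gradient decreases monotonically along the cascade within every event;
#' dry events impose stronger environmental differences and weaker
#' downstream mixing than rainy events.  Communities are assembled by
#' Gaussian filtering of a lognormal pool on Brownian niche traits, with
#' each reservoir's pool mixing in the upstream community at rate m
#' (unidirectional hydrological dispersal).  An environmental table with
#' five correlated variables (trophic index, total nitrogen, total
#' phosphorus, DOC, temperature plus residence time contrasts) is emitted
#' alongside.
#'
#' @param seed master seed.
#' @param n_taxa tree size (default 150).
#' @param J reads per sample (default 1000).
#' @param season_shift displacement of all rainy-season environmental optima,
#'   in units of the tip-trait standard deviation (default 0.8).  Emulates
#'   the seasonal change in temperature and flow that moves the whole
#'   community, so that samples separate by season as well as along the
#'   cascade.
#' @return list of class \code{synthetic_dataset} with elements \code{tree},
#'   \code{traits}, \code{table} (24 x n_taxa [otu_table]), \code{metadata},
#'   \code{env} (numeric matrix), \code{design} ([cascade_design()]),
#'   \code{truth} (dominant generating regime per season).
#' @export
generate_cascade_study <- function(seed = 1L, n_taxa = 150, J = 1000,
                                   season_shift = 2) {
  design <- cascade_design()
  tree <- simulate_tree(n_taxa, derive_seed(seed, "tree"))
  traits <- evolve_trait(tree, sigma2 = 1, root_value = 0,
                         seed = derive_seed(seed, "trait"))
  set.seed(derive_seed(seed, "pool"))
  pool <- .lognormal_pool(n_taxa)
  names(pool) <- tree$tip.label
  tr_sd <- stats::sd(traits)
  tr_mean <- mean(traits)
  # trophic optimum positions along the cascade, in trait units
  grad <- c(BB = 1.5, Pr = 0.5, `NA` = -0.5, TI = -1.5)

  samples <- character(0)
  counts <- NULL
  md <- NULL
  env_rows <- NULL
  for (ev in design$events) {
    season <- season_of_event(ev)
    g_scale <- if (season == "dry") 1.0 else 0.4       # gradient strength
    m <- if (season == "dry") 0.15 else 0.6            # upstream mixing rate
    sigma <- if (season == "dry") 0.7 else 1.4         # filter width
    shift <- if (season == "dry") 0 else season_shift  # seasonal displacement
    set.seed(derive_seed(seed, "event", ev))
    jitter <- rnorm(length(design$reservoirs), 0, 0.1)
    upstream <- NULL
    for (ri in seq_along(design$reservoirs)) {
      res <- design$reservoirs[ri]
      sid <- paste(res, ev, sep = "_")
      env_opt <- tr_mean + (grad[res] * g_scale + shift + jitter[ri]) * tr_sd
      local_pool <- if (is.null(upstream)) pool else (1 - m) * pool + m * upstream
      x <- assemble_community(local_pool / sum(local_pool), traits, env_opt,
                              sigma, J, derive_seed(seed, "comm", sid))
      upstream <- x / sum(x)
      counts <- rbind(counts, x)
      samples <- c(samples, sid)
      md <- rbind(md, data.frame(sample_id = sid, reservoir = res, event = ev,
                                 season = season, fraction = "FL",
                                 subcommunity = "FL", stringsAsFactors = FALSE))
      trophic <- grad[res] * g_scale + jitter[ri]
      env_rows <- rbind(env_rows, data.frame(
        sample_id = sid,
        trophic_index = trophic,
        total_nitrogen = 2 + 0.8 * trophic + rnorm(1, 0, 0.05),
        total_phosphorus = 1 + 0.6 * trophic + rnorm(1, 0, 0.05),
        doc = 5 + 1.2 * trophic + rnorm(1, 0, 0.1),
        temperature = (if (season == "dry") 22 else 28) + rnorm(1, 0, 0.5),
        residence_time = (if (season == "dry") 90 else 30) + 10 * trophic + rnorm(1, 0, 3),
        stringsAsFactors = FALSE))
    }
  }
  rownames(counts) <- samples
  table <- otu_table(counts, taxon_ids = tree$tip.label)
  env <- as.matrix(env_rows[, -1])
  rownames(env) <- env_rows$sample_id
  truth <- data.frame(season = c("dry", "rainy"),
                      regime = c("selection", "homogenizing_dispersal"),
                      stringsAsFactors = FALSE)
  structure(list(tree = tree, traits = traits, table = table, metadata = md,
                 env = env, design = design, truth = truth, seed = seed),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to a directory
#'
#' Emits tree (newick), OTU table, metadata, environmental table and truth
#' as plain-text files.
#'
#' @param x a \code{synthetic_dataset}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_synthetic_dataset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tree(x$tree, file.path(dir, "tree.nwk"))
  write_otu_table(x$table, file.path(dir, "otu_table.tsv"))
  write.table(x$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(x$env)) {
    env <- data.frame(sample_id = rownames(x$env), x$env, check.names = FALSE)
    write.table(env, file.path(dir, "env.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(x$truth)) {
    truth <- if (is.data.frame(x$truth)) x$truth else data.frame(truth = x$truth)
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
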