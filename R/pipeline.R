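#' Pipeline configuration
#'
#' Collects every input and tunable of the full analysis.  Inputs may be
#' given as file paths or as in-memory objects ([otu_table], \code{phylo},
#' data.frame, matrix).
#'
#' @param table OTU table (path or [otu_table]).
#' @param tree rooted phylogeny (path or \code{phylo}).
#' @param metadata sample metadata (path or data.frame).
#' @param env optional environmental table (path or numeric matrix).
#' @param rarefy_depth \code{"min"} (rarefy to the minimum sample total, the
#'   default), a positive integer depth, or \code{NULL} to skip rarefaction.
#' @param n_iter_bnti,n_iter_rc null-model iteration counts (default 999).
#' @param bnti_cut,rc_cut classification thresholds (defaults 2 and 0.95).
#' @param design a [cascade_design()].
#' @param prune_to_tree drop table taxa absent from the tree instead of
#'   erroring.
#' @param n_perm PERMANOVA permutations (default 999).
#' @param seed master seed for every random stage.
#' @param out_dir output directory, or \code{NULL} to skip writing files.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(table, tree, metadata, env = NULL,
                            rarefy_depth = "min",
                            n_iter_bnti = 999, n_iter_rc = 999,
                            bnti_cut = 2, rc_cut = 0.95,
                            design = cascade_design(),
                            prune_to_tree = FALSE,
                            n_perm = 999, seed = 1L, out_dir = NULL) {
  if (bnti_cut <= 0 || rc_cut <= 0) stop("classification thresholds must be positive")
  structure(list(table = table, tree = tree, metadata = metadata, env = env,
                 rarefy_depth = rarefy_depth,
                 n_iter_bnti = n_iter_bnti, n_iter_rc = n_iter_rc,
                 bnti_cut = bnti_cut, rc_cut = rc_cut, design = design,
                 prune_to_tree = prune_to_tree, n_perm = n_perm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.load_input <- function(x, reader) if (is.character(x) && length(x) == 1) reader(x) else x

#' Run the full community-assembly analysis
#'
#' rarefy -> betaMNTD -> betaNTI -> RC-bray -> classification -> Local /
#' Regional / Stochastic summaries, plus PERMANOVA by season and by
#' reservoir within season, NMDS for significant groupings, and PCA of the
#' environmental table when given.  Raup-Crick runs per season: the
#' metacommunity defining occupancy and abundance weights is the analyzed
#' season's table, and only pairs not already classified as selection are
#' evaluated.  Every random stage draws from a stream derived from
#' \code{config$seed}, so a rerun with the same config reproduces identical
#' numbers.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with \code{table} (as analyzed), \code{pairs}
#'   (per-pair data.frame: event, season, reservoirs, betaMNTD, betaNTI,
#'   RC-bray, label), \code{summaries} (per season and total
#'   [summarize_processes()] results), \code{bmntd}, \code{stats}
#'   (PERMANOVA / NMDS / PCA results) and \code{manifest}.  If
#'   \code{config$out_dir} is set, per-pair TSV, JSON summary, stats TSVs
#'   and a manifest JSON are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  table <- .stage("read_inputs", as_otu_table(.load_input(config$table, read_otu_table)))
  tree <- .stage("read_inputs", validate_tree(.load_input(config$tree, read_tree)))
  metadata <- .stage("read_inputs", .load_input(config$metadata, read_metadata))
  env <- if (!is.null(config$env)) .stage("read_inputs", .load_input(config$env, read_env_table))

  table <- .stage("prune", prune_to_tree(table, tree, prune = config$prune_to_tree))
  if (!is.null(config$rarefy_depth)) {
    depth <- if (identical(config$rarefy_depth, "min")) NULL else config$rarefy_depth
    table <- .stage("rarefy", rarefy(table, depth = depth, seed = derive_seed(config$seed, "rarefy")))
  }
  metadata <- .stage("metadata", align_metadata(metadata, table))

  D <- .stage("turnover", cophenetic_distances(tree))
  bm <- .stage("turnover", beta_mntd(table, D, abundance_weighted = TRUE))

  all_pairs <- .stage("pairs", connected_pairs(metadata, config$design))
  results <- NULL
  for (season in unique(all_pairs$season)) {
    sp <- all_pairs[all_pairs$season == season, , drop = FALSE]
    season_samples <- metadata$sample_id[metadata$season == season]
    season_table <- otu_table(.otu_counts(table)[season_samples, , drop = FALSE])
    season_table <- otu_table(.otu_counts(season_table)[, colSums(season_table) > 0, drop = FALSE])
    bn <- .stage("bnti", beta_nti(season_table, D, n_iter = config$n_iter_bnti,
                                  seed = config$seed,
                                  pairs = sp[, c("sample_a", "sample_b")]))
    need_rc <- is.na(bn$bnti) | abs(bn$bnti) <= config$bnti_cut
    rc <- rep(NA_real_, nrow(bn))
    bc <- rep(NA_real_, nrow(bn))
    if (any(need_rc)) {
      rcres <- .stage("rc", raup_crick_bray(season_table,
                                            pairs = sp[need_rc, c("sample_a", "sample_b")],
                                            n_iter = config$n_iter_rc, seed = config$seed))
      rc[need_rc] <- rcres$rc_bray
      bc[need_rc] <- rcres$bc_obs
    }
    label <- .stage("classify", classify_pair(bn$bnti, rc, config$bnti_cut, config$rc_cut))
    results <- rbind(results,
                     cbind(sp, bmntd_obs = bn$bmntd_obs, null_mean = bn$null_mean,
                           null_sd = bn$null_sd, bnti = bn$bnti, bc_obs = bc,
                           rc_bray = rc, label = as.character(label)))
  }

  summaries <- lapply(split(results$label, results$season), summarize_processes)
  summaries$total <- summarize_processes(results$label)

  stats <- list()
  stats$permanova_season <- .stage("stats", permanova(bm, metadata$season,
                                                      n_perm = config$n_perm,
                                                      seed = derive_seed(config$seed, "perm_season")))
  for (season in unique(metadata$season)) {
    sel <- metadata$season == season
    stats[[paste0("permanova_reservoir_", season)]] <-
      .stage("stats", permanova(bm[sel, sel], metadata$reservoir[sel],
                                n_perm = config$n_perm,
                                seed = derive_seed(config$seed, "perm_res", season)))
  }
  stats$nmds <- if (stats$permanova_season$p_value < 0.05)
    .stage("stats", nmds(bm, k = 2, seed = derive_seed(config$seed, "nmds")))
  if (!is.null(env)) {
    env <- env[rownames(table)[rownames(table) %in% rownames(env)], , drop = FALSE]
    stats$pca <- .stage("stats", pca_env(env))
  }

  manifest <- list(package = "phylocascade",
                   version = as.character(packageVersion("phylocascade")),
                   seed = config$seed,
                   n_iter_bnti = config$n_iter_bnti, n_iter_rc = config$n_iter_rc,
                   bnti_cut = config$bnti_cut, rc_cut = config$rc_cut,
                   n_perm = config$n_perm,
                   rarefy_depth = if (is.null(config$rarefy_depth)) "none" else as.character(config$rarefy_depth),
                   n_samples = nrow(table), n_taxa = ncol(table),
                   cascade = config$design$reservoirs)

  out <- list(table = table, pairs = results, summaries = summaries,
              bmntd = bm, stats = stats, manifest = manifest)
  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, config$out_dir)
  invisible(out)
}

.write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(out$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ <- lapply(out$summaries, function(s)
    list(n_pairs = s$n_pairs, counts = as.list(s$counts),
         fractions = as.list(s$fractions), percents = as.list(s$percents)))
  jsonlite::write_json(summ, file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  bm <- data.frame(sample_id = rownames(out$bmntd), out$bmntd, check.names = FALSE)
  write.table(bm, file.path(dir, "bmntd.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  perma <- do.call(rbind, lapply(names(out$stats)[grepl("^permanova", names(out$stats))], function(nm) {
    s <- out$stats[[nm]]
    data.frame(analysis = nm, pseudo_f = s$pseudo_f, r_squared = s$r_squared,
               p_value = s$p_value, n_perm = s$n_perm)
  }))
  write.table(perma, file.path(dir, "permanova.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$stats$nmds)) {
    pts <- data.frame(sample_id = rownames(out$stats$nmds$points), out$stats$nmds$points)
    write.table(pts, file.path(dir, "nmds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$stats$pca)) {
    sc <- data.frame(sample_id = rownames(out$stats$pca$scores), out$stats$pca$scores)
    write.table(sc, file.path(dir, "pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Lay out per-pair classifications in the reservoir-by-event summary layout
#'
#' Rows are adjacent reservoir pairs, columns are sampling events; per-season
#' and overall Local / Regional / Stochastic percentages are appended.
#'
#' @param classified data.frame with columns \code{event},
#'   \code{reservoir_a}, \code{reservoir_b}, \code{label} (e.g. the
#'   \code{pairs} element of [run_pipeline()]'s result).
#' @param design a [cascade_design()].
#' @return list of class \code{table1_summary}: \code{layout} (pairs x
#'   events character matrix), \code{summaries} (data.frame with one row per
#'   season plus \code{total}: percents and raw fractions).
#' @export
summarize_table1 <- function(classified, design = cascade_design()) {
  adj <- adjacent_reservoirs(design)
  pair_names <- paste(adj[, 1], adj[, 2], sep = " - ")
  layout <- matrix(NA_character_, nrow(adj), length(design$events),
                   dimnames = list(pair_names, design$events))
  for (i in seq_len(nrow(adj))) {
    for (ev in design$events) {
      hit <- classified$label[classified$reservoir_a == adj[i, 1] &
                              classified$reservoir_b == adj[i, 2] &
                              classified$event == ev]
      if (length(hit) != 1)
        stop(sprintf("missing classification for pair %s, event %s", pair_names[i], ev))
      layout[i, ev] <- as.character(hit)
    }
  }
  seasons <- season_of_event(design$events)
  rows <- lapply(unique(seasons), function(se) {
    s <- summarize_processes(layout[, seasons == se, drop = FALSE])
    data.frame(season = se, local_pct = s$percents["local"],
               regional_pct = s$percents["regional"],
               stochastic_pct = s$percents["stochastic"],
               local_frac = s$fractions["local"], regional_frac = s$fractions["regional"],
               stochastic_frac = s$fractions["stochastic"], n_pairs = s$n_pairs,
               row.names = NULL)
  })
  s <- summarize_processes(layout)
  rows$total <- data.frame(season = "total", local_pct = s$percents["local"],
                           regional_pct = s$percents["regional"],
                           stochastic_pct = s$percents["stochastic"],
                           local_frac = s$fractions["local"],
                           regional_frac = s$fractions["regional"],
                           stochastic_frac = s$fractions["stochastic"],
                           n_pairs = s$n_pairs, row.names = NULL)
  structure(list(layout = layout, summaries = do.call(rbind, rows)),
            class = "table1_summary")
}

#' @export
print.table1_summary <- function(x, ...) {
  print(x$layout)
  df <- x$summaries
  for (i in seq_len(nrow(df)))
    cat(sprintf("%-6s Local: %d%%  Regional: %d%%  Stochastic: %d%%  (n = %d)\n",
                df$season[i], df$local_pct[i], df$regional_pct[i],
                df$stochastic_pct[i], df$n_pairs[i]))
  invisible(x)
}
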