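test_that("the two-stage rule maps (betaNTI, RC) to process labels exactly", {
  expect_equal(as.character(classify_pair(3.1, NA)), "S")
  expect_equal(as.character(classify_pair(-2.5, NA)), "S")   # sign lumped into S
  expect_equal(as.character(classify_pair(-1.0, -0.97)), "HD")
  expect_equal(as.character(classify_pair(1.2, 0.96)), "DL")
  expect_equal(as.character(classify_pair(0.5, 0.2)), "D")

  # strict inequalities: boundary values fall to the less specific branch
  expect_equal(as.character(classify_pair(2, 0.2)), "D")
  expect_equal(as.character(classify_pair(-2, 0.2)), "D")
  expect_equal(as.character(classify_pair(0, 0.95)), "D")
  expect_equal(as.character(classify_pair(0, -0.95)), "D")
  expect_equal(as.character(classify_pair(2.0000001, NA)), "S")

  # an undefined betaNTI forwards to the RC stage
  expect_equal(as.character(classify_pair(NA, 0.99)), "DL")

  # RC never alters a selection call
  expect_equal(as.character(classify_pair(rep(4, 3), c(-1, 0, 1))), rep("S", 3))

  expect_error(classify_pair(1.5, NA), "RC-bray value required")

  v <- classify_pair(c(3, -1, 0.1), c(NA, -0.99, 0.5))
  expect_equal(as.character(v), c("S", "HD", "D"))
  expect_equal(levels(v), c("S", "HD", "DL", "D"))
})

make_metadata <- function(reservoirs = c("BB", "Pr", "NA", "TI"),
                          events = c("D1", "D2", "D3", "R1", "R2", "R3")) {
  g <- expand.grid(reservoir = reservoirs, event = events,
                   stringsAsFactors = FALSE)
  g$sample_id <- paste(g$reservoir, g$event, sep = "_")
  g$season <- season_of_event(g$event)
  g
}

test_that("connected pairs follow the cascade within each event", {
  md <- make_metadata()
  pairs <- connected_pairs(md, cascade_design())
  expect_equal(nrow(pairs), 18)
  expect_equal(sum(pairs$season == "dry"), 9)
  expect_equal(sum(pairs$season == "rainy"), 9)

  # never spans events, never skips a reservoir
  expect_true(all(vapply(seq_len(nrow(pairs)), function(i) {
    ea <- md$event[md$sample_id == pairs$sample_a[i]]
    eb <- md$event[md$sample_id == pairs$sample_b[i]]
    ea == eb && ea == pairs$event[i]
  }, logical(1))))
  order_idx <- match(pairs$reservoir_a, c("BB", "Pr", "NA", "TI"))
  expect_true(all(match(pairs$reservoir_b, c("BB", "Pr", "NA", "TI")) == order_idx + 1))

  # generated designs: adjacency is exhaustive and exact
  for (k in 2:5) {
    res <- paste0("R", seq_len(k))
    evs <- c("D1", "R1")
    d <- cascade_design(res, evs)
    p <- connected_pairs(make_metadata(res, evs), d)
    expect_equal(nrow(p), (k - 1) * 2)
    expect_equal(unique(paste(p$reservoir_a, p$reservoir_b))[seq_len(k - 1)],
                 paste(res[-k], res[-1]))
  }

  md_missing <- md[md$sample_id != "Pr_D2", ]
  expect_error(connected_pairs(md_missing), "reservoir=Pr, event=D2")
  md_dup <- rbind(md, md[md$sample_id == "BB_D1", ])
  expect_error(connected_pairs(md_dup), "multiple samples")
})

test_that("process summaries aggregate to Local / Regional / Stochastic", {
  all_drift <- summarize_processes(rep("D", 9))
  expect_equal(unname(all_drift$percents), c(0, 0, 100))

  fl_dry <- summarize_processes(c("DL", "HD", "HD", "S", "S", "S", "DL", "HD", "S"))
  expect_equal(unname(fl_dry$percents["regional"]), 56)
  expect_equal(unname(fl_dry$percents["local"]), 44)

  for (seed in 1:5) {
    set.seed(seed)
    labs <- sample(c("S", "HD", "DL", "D"), 9, replace = TRUE)
    s <- summarize_processes(labs)
    expect_equal(sum(s$fractions), 1)
    expect_equal(sum(s$counts), s$n_pairs)
    # permutation invariance
    s2 <- summarize_processes(sample(labs))
    expect_equal(s$percents, s2$percents)
  }
  expect_error(summarize_processes(character(0)), "empty")
  expect_error(summarize_processes(c("D", "XX")), "unknown process label")
})

test_that("the summary-table layout is self-consistent with the raw fractions", {
  md <- make_metadata()
  pairs <- connected_pairs(md)
  set.seed(8)
  pairs$label <- sample(c("S", "HD", "DL", "D"), nrow(pairs), replace = TRUE)
  t1 <- summarize_table1(pairs)
  expect_equal(dim(t1$layout), c(3, 6))
  expect_false(anyNA(t1$layout))

  # percentages recomputed from the layout equal the summary rows
  for (se in c("dry", "rainy")) {
    evs <- colnames(t1$layout)[season_of_event(colnames(t1$layout)) == se]
    s <- summarize_processes(t1$layout[, evs])
    row <- t1$summaries[t1$summaries$season == se, ]
    expect_equal(row$local_pct, unname(s$percents["local"]))
    expect_equal(row$regional_pct, unname(s$percents["regional"]))
    expect_equal(row$stochastic_pct, unname(s$percents["stochastic"]))
  }
  tot <- t1$summaries[t1$summaries$season == "total", ]
  expect_equal(tot$local_frac + tot$regional_frac + tot$stochastic_frac, 1)

  all_d <- pairs
  all_d$label <- "D"
  td <- summarize_table1(all_d)
  expect_true(all(td$summaries$stochastic_pct == 100))

  expect_error(summarize_table1(pairs[-1, ]), "missing classification")
})
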