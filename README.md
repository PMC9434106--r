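# phylocascade

Partitions microbial community turnover between connected habitats into the
four assembly processes of metacommunity theory — **selection (S)**,
**homogenizing dispersal (HD)**, **dispersal limitation (DL)** and **drift
(D)** — using the two-stage phylogenetic null-model framework, and applies
it to the design of a cascade of four connected reservoirs (BB → Pr → NA →
TI) sampled over three dry and three rainy events.  It is written for
microbial ecologists who have an OTU table, a rooted phylogeny of the OTUs
and sample metadata, and want per-pair process labels plus the supporting
ordination statistics.

## The method

For communities A and B with relative abundances *f* and patristic tip
distances *d*, the abundance-weighted beta mean nearest taxon distance is

```
betaMNTD(A,B) = 1/2 [ sum_{i in A} f_i min_{j in B} d_ij
                    + sum_{j in B} f_j min_{i in A} d_ij ]
```

**Stage 1:** a tip-shuffle null (taxon identities permuted across the
phylogeny, 999 iterations) turns the observed betaMNTD into a z-score, the
beta nearest taxon index; `|betaNTI| > 2` assigns selection.
**Stage 2:** remaining pairs get the abundance-based Raup–Crick index with
Bray–Curtis (`RC_bray`, scaled to [−1, 1]): each null iteration reassembles
both samples from the metacommunity preserving observed richness and total
abundance.  `RC < −0.95` assigns homogenizing dispersal, `RC > 0.95`
dispersal limitation, intermediate values drift.  Labels for the three
adjacent reservoir pairs × three events per season aggregate into Local
(S) / Regional (HD+DL) / Stochastic (D) percentages.

PERMANOVA and NMDS on the betaMNTD matrix and a PCA of standardized
environmental variables reproduce the survey-level statistics.  A
seed-deterministic simulator (Yule tree, Brownian niche traits, Gaussian
environmental filtering of a lognormal pool) generates the full cascade
design and single-process benchmark scenarios, so everything is testable
without sequence data.

## Worked example

```r
library(phylocascade)

cs  <- generate_cascade_study(seed = 42, n_taxa = 60, J = 500)
cfg <- pipeline_config(table = cs$table, tree = cs$tree,
                       metadata = cs$metadata, env = cs$env,
                       n_iter_bnti = 199, n_iter_rc = 199,
                       n_perm = 199, seed = 42)
res <- run_pipeline(cfg)
summarize_table1(res$pairs, cs$design)
```

```
        D1   D2  D3   R1   R2  R3
BB - Pr "D"  "D" "DL" "D"  "D" "D"
Pr - NA "S"  "S" "D"  "HD" "D" "HD"
NA - TI "DL" "D" "DL" "D"  "D" "D"
dry    Local: 22%  Regional: 33%  Stochastic: 44%  (n = 9)
rainy  Local: 0%  Regional: 22%  Stochastic: 78%  (n = 9)
total  Local: 11%  Regional: 28%  Stochastic: 61%  (n = 18)
```

Each cell is the process governing the turnover between two directly
connected reservoirs at one sampling event; the summary rows are the
Local/Regional/Stochastic percentages per season.  Under the generator's
conditions the dry season (strong trophic gradient, weak mixing) shows
selection and dispersal limitation while the rainy season (homogenized
environment, strong flow) is dominated by drift and homogenizing dispersal.

```r
res$stats$permanova_season
#> PERMANOVA: pseudo-F = 7.902, R2 = 0.2643 (26.43%), p = 0.02 (199 permutations)
res$stats$permanova_reservoir_rainy
#> PERMANOVA: pseudo-F = -0.820, R2 = -0.4441 (-44.41%), p = 0.93 (199 permutations)
res$stats$nmds
#> NMDS: 24 points in 2 dimensions, stress = 0.0277
```

Season explains a significant 26% of the betaMNTD dissimilarity; within
the rainy season the reservoirs are statistically indistinguishable —
the same qualitative pattern as in the field data the design emulates.

A thin command-line wrapper ships in `inst/scripts/phylocascade.R`
(subcommands `simulate` and `run-all`).

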