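---
title: "Partitioning community assembly processes along a reservoir cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning community assembly processes along a reservoir cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocascade)
```

## The question and the method

Microbial community turnover between connected habitats can be driven by
*local* processes (environmental and biotic selection), *regional* processes
(dispersal, either so intense that it homogenizes communities or so
restricted that it isolates them), or by purely stochastic demographic
*drift*. phylocascade implements the two-stage phylogenetic null-model
procedure that assigns one of these processes to every pair of communities,
and aggregates the assignments over a cascade of connected reservoirs
sampled repeatedly across dry and rainy seasons.

The procedure rests on one biological assumption: **niche conservatism** —
closely related taxa occupy similar habitats, so phylogenetic turnover
between communities carries information about habitat filtering.  Both
stages consume an OTU abundance table and a rooted, branch-length-bearing
phylogeny whose tips are the OTUs.

**Stage 1 — selection.**  The abundance-weighted *beta mean nearest taxon
distance* between communities A and B is

$$\beta MNTD(A,B) = \frac12\left[\sum_{i \in A} f_i \min_{j \in B} d_{ij} +
\sum_{j \in B} f_j \min_{i \in A} d_{ij}\right],$$

where $f_i$ are relative abundances and $d_{ij}$ the patristic (cophenetic)
distance between tips.  A taxon present in both communities matches itself
at distance zero, so $\beta MNTD(A,A)=0$.  The null model shuffles taxon
identities across the tips of the phylogeny (one permutation of the full
taxa pool per iteration, shared by all pairs) and recomputes the metric; the
z-score of the observed value against the null distribution is the *beta
nearest taxon index*, $\beta NTI$.  $|\beta NTI| > 2$ indicates selection
(the sign separating variable from homogeneous selection is retained in the
output but lumped into a single label, matching how the field survey reports it).

**Stage 2 — dispersal vs. drift.**  Pairs not classified by selection go to
an abundance-based Raup–Crick test using Bray–Curtis dissimilarity.  Each
null iteration reassembles both communities from the metacommunity,
preserving each sample's richness (membership drawn without replacement with
probability proportional to occupancy) and total abundance (each drawn taxon
seeds one individual, the remainder assigned multinomially by metacommunity
relative abundance).  With $\alpha$ the fraction of null Bray–Curtis values
below the observed one (ties counted half), $RC_{bray} = 2\alpha - 1 \in
[-1, 1]$.  $RC < -0.95$ is homogenizing dispersal, $RC > 0.95$ dispersal
limitation, intermediate values drift.  All four inequalities are strict;
boundary values fall to the less specific process.

**Aggregation.**  Only directly connected reservoir pairs are compared
(BB–Pr, Pr–NA, NA–TI), within each sampling event: three pairs per event,
nine per season.  Labels summarize as Local = S, Regional = HD + DL,
Stochastic = D, as percentages rounded half away from zero (raw fractions
are retained; several of the survey's reported cells are off by one point from
any consistent rounding, and the package reproduces only the arithmetically
consistent ones).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_iter` (both nulls) | 999 | null iterations; the framework's convention, giving p-granularity 1/999 |
| `bnti_cut` | 2 | two-sided z threshold for selection |
| `rc_cut` | 0.95 | two-sided RC threshold for dispersal |
| rarefaction depth | min sample total | even sequencing effort before any comparison |
| `n_perm` (PERMANOVA) | 999 | free permutations of sample labels; the design has no stated blocking structure |
| NMDS restarts | 20 | random starts; convergence at stress improvement < 1e-6 or 500 iterations |

Determinism: every random stage derives its own stream from one master seed
by hashing stream labels and entity identifiers (`derive_seed`).  Rarefying
one sample, or evaluating pairs in a different order, never changes the
draws made for any other sample or pair; `RC(a, b)` and `RC(b, a)` are
bit-identical because the pair stream is keyed on the sorted ids.

Numerical choices: Bray–Curtis ties in the RC null are detected with a
1e-12 tolerance (exact equality is floating-point fragile); a degenerate
$\beta NTI$ null (sd = 0, e.g. a single shared taxon) yields `NA` with a
warning and the pair is forwarded to the RC stage; taxa present in the
table but absent from the tree are an error unless pruning is explicitly
requested, because silent pruning hides upstream mistakes.

## What the synthetic data emulate

The survey's raw sequence data are not required by any test: the
`synthetic_data` generators produce the survey's design de novo.

`generate_cascade_study()` emulates 4 reservoirs × 6 events (3 dry, 3
rainy): a Yule phylogeny (150 tips by default), Brownian-motion niche
traits (the minimal mechanism producing phylogenetically conserved habitat
preferences), a heavy-tailed lognormal regional pool, and per-reservoir
Gaussian environmental filtering with unidirectional upstream mixing.  Dry
events get the full trophic gradient, weak mixing (m = 0.15) and a narrow
filter (sigma = 0.7 trait units); rainy events get a flattened gradient
(×0.4), strong mixing (m = 0.6), a wide filter (sigma = 1.4) and a
season-wide displacement of every optimum by 2 trait-sd (the
temperature/flow change that moves the whole community, so samples
separate by season as well as along the cascade) — the hydrological
contrast the survey describes.  A five-variable environmental
table (trophic index, total N, total P, DOC, temperature, residence time)
tracks the gradient for the PCA stage.

`generate_scenario()` produces focal pairs with a known generating process,
plus four unfiltered *context* samples drawn from lognormally perturbed
copies of the pool.  The context matters: the Raup–Crick null takes its
occupancy and abundance weights from the whole table, and with only the
focal pair as metacommunity the null reassembles near-copies of the pair,
leaving homogenizing dispersal undetectable in principle.  The real
analysis always judges a reservoir pair against a full season's table; the
context samples reproduce that situation at scenario scale.

The strong-effect defaults were fixed once by the end-to-end recovery
experiment (the acceptance suite reruns it at 50 replicate pairs per
process, 999 null iterations) and then frozen:

* selection: J = 2000, filter sigma = 0.5 trait units, environment offset
  Delta = 4 (the Brownian tip-trait sd is about 2, so the two optima are
  about two trait-sd apart);
* homogenizing dispersal: two draws of J = 4000 from one identical pool
  (J at least 10 × n_taxa; pushing J far higher saturates per-sample
  richness, which removes the membership noise the null needs and weakens
  the signal again);
* dispersal limitation: pools on phylogenetically random half-size supports
  sharing 10% of taxa — random, not clustered, so the RC signal is isolated
  from any betaNTI signal;
* drift: pair pools are two *weakly* perturbed copies of the regional pool
  (perturbation sd 0.25 vs. 1 for the context), a demographic-drift
  realization whose dissimilarity sits inside the null distribution.  A
  literal same-pool pair at large J is already homogenized (RC near −1),
  which is the HD signature, not drift — the weak perturbation is what
  makes drift mean "indistinguishable from null" here.

The pool's lognormal sd of 2 keeps per-sample richness well below
metacommunity richness; RC membership nulls lose their discriminating noise
when every sample contains every taxon.

What the generator does **not** emulate: sequencing error and chimeras,
OTU-clustering artifacts, compositionality of relative counts, tree
estimation error (the tree is known without error), seasonal succession
within a season, and any feedback of communities on their environment.
Passing the recovery tests therefore shows the inference machinery is
correct and calibrated under its own assumptions — not that real reservoir
data meet those assumptions.

## Supporting statistics

PERMANOVA (one factor, Anderson's partition of squared distances, delegated
to `vegan::adonis2`) runs on the betaMNTD matrix twice, mirroring the
survey: all samples grouped by season, then each season grouped by
reservoir.  NMDS (`vegan::metaMDS`, Kruskal stress-1) ordinates groupings
that test significant; PCA of z-scored environmental variables
(`stats::prcomp`) summarizes the gradient, with each axis oriented so its
largest-magnitude loading is positive, for reproducible output.  The
acceptance suite checks the PERMANOVA machinery by exhaustive enumeration
on six samples and by its empirical type-I error (5% ± 2% at alpha = 0.05
over 1000 exchangeable simulations), and PCA against an independent
eigendecomposition.

## Problem sizes used by the shipped tests

Unit tests run on 2–25-taxa fixtures built in code.  The acceptance suite
uses 100 replicate two-sample metacommunities (100 taxa, J = 1000) for the
betaNTI false-positive rate, 100 drift scenarios for RC centering, 50
replicate pairs per process (200 taxa) for recovery, a 60-taxa cascade for
the end-to-end run, and 1000 simulations (12 samples each) for the
PERMANOVA calibration — sizes at which every documented property is
measurable with comfortable statistical margins.

## Known limitations

* The betaNTI tip shuffle permutes the full taxa pool of the supplied
  distance matrix.  If the tree is much larger than the analyzed table, the
  null is diluted; prune inputs to the metacommunity of interest.
* RC-bray requires integer counts (it reassembles individuals); rarefied
  tables satisfy this by construction, relative abundances do not.
* Process labels are per-pair and categorical; the package does not
  attribute processes to individual taxa or quantify selection strength.
* With very small n_iter the z-score and the RC quantile are coarse;
  999 is the intended operating point.
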