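---
title: "Group-level structural covariance network analysis with scnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level structural covariance network analysis with scnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The model

A structural covariance network (SCN) is a group-level graph over brain
regions. Its input is nothing more than a table: one row per subject, one
column of gray-matter volume (GMV, mm³) per region of interest — here the 90
cortical and subcortical nodes of the AAL parcellation (see
`aal90_regions()`). For each group separately, the edge weight between
regions $i$ and $j$ is the Pearson correlation $r_{ij}$ of their volumes
across that group's subjects, computed after the volumes have been
residualized (pooled across groups, ordinary least squares) on age, sex, and
total intracranial volume. Covariance of regional anatomy across people is
the measured quantity; the residualization step ensures it is not an
artifact of everyone's head size or age.

Because a single correlation threshold yields different edge counts in
different groups — and almost every graph metric depends strongly on edge
count — groups are compared at matched **density**
$D = E / [N(N-1)/2]$. `threshold_density()` keeps exactly
$E = \operatorname{round}(D \cdot N(N-1)/2)$ edges with the largest
(positive) correlations, and the analysis repeats over the grid
$D = 0.33, 0.34, \dots, 0.50$. The floor is the smallest grid density at
which both group networks stay fully connected (`min_connected_density()`
verifies this on the data at hand); the ceiling reflects the usual judgment
that binary brain graphs above half density stop being interpretable.
Within one correlation matrix the edge sets are nested along the grid, so
every per-density quantity is a curve, summarized by its trapezoidal area
(AUC) for threshold-free comparison.

## Metrics and normalization

On each binary graph the package computes, per density:

* mean local clustering $C_p$ and **transitivity** (3 × triangles /
  connected triples) — segregation;
* harmonic-mean characteristic path length
  $L_p = N(N-1) \big/ \sum_{i \ne j} d_{ij}^{-1}$ and global efficiency
  $E_{glob} = 1/L_p$ — integration. The harmonic form makes disconnected
  pairs contribute zero rather than infinity, so fragmented graphs need no
  special casing, and $E_{glob} \cdot L_p = 1$ holds exactly (this identity
  is tested);
* local efficiency (mean harmonic efficiency of each node's
  neighbor-induced subgraph), degree assortativity, and modularity $Q$;
* per node: degree, local clustering, and betweenness centrality normalized
  by $(N-1)(N-2)/2$.

Small-world parameters normalize against chance at matched degree sequence:
$m = 20$ networks (default) are generated per density by double-edge-swap
rewiring (10 attempted swaps per edge), and
$\gamma = C_p/C_{rand}$, $\lambda = L_p/L_{rand}$,
$\sigma = \gamma/\lambda$. Each density point uses its own ensemble.
Graphs too rigid to swap (complete graphs are the extreme case) return an
ensemble of identical copies with a warning rather than an error, which
pins $\gamma = \lambda = 1$ there by construction.

Modularity uses igraph's greedy agglomerative optimizer
(`cluster_fast_greedy`). That algorithm is deterministic, so repeated runs
are bit-for-bit identical without seeding; the `modularity_seed` argument is
retained in the interface for forward compatibility with stochastic
optimizers but currently changes nothing.

## Inference

Group differences are assessed by label permutation: subjects are reassigned
to two pseudo-groups of the original sizes, and the *entire* pipeline —
correlation, thresholding, metric — is recomputed per permutation (1,000 by
default). Residualization is *not* refit per permutation: covariates are
group-agnostic, it is estimated once on the pooled cohort, which keeps the
permutation null exchangeable and the test exact. Two-tailed p-values use
the add-one rule $p = (1 + \#\{|t^\ast| \ge |t|\})/(1 + n_{perm})$, so $p$
is never zero. The permutation stream canonically samples the smaller
group's index set, which makes results invariant to swapping the group
labels (differences negate; p-values are unchanged).

Benjamini–Hochberg FDR control at $q = 0.05$ is applied within families
that mirror how such results are reported: per metric across the 18 grid
densities (global per-density scope), per metric across the 90 nodes (nodal
scopes), and across metrics for the AUC summaries. Nodal inference runs
both at the grid floor $D_{min}$ and on per-node AUCs; the two emphasize
different things (a single interpretable operating point vs. threshold-free
aggregation) and both are reported.

Hubs are nodes whose betweenness exceeds the network mean by more than two
sample standard deviations; the basis is the AUC of betweenness over the
grid. Robustness is probed by sequential node removal — targeted (highest
current degree, recomputed after each removal, ties to the lowest node
index) versus random (averaged over 100 seeded orders) — tracking the
largest connected component as a fraction of the original $N$; the area
under that curve is the scalar summary, since qualitative "stability"
claims need a number to be testable.

## The synthetic cohort generator

`simulate_cohort()` replaces the study's MRI-derived table. It draws
multivariate-normal ROI vectors with a block-constant target correlation:
`rho_within` inside each of six 15-region modules, `rho_between` elsewhere,
a group-1 boost `delta` for planted effects, and optional global-connector
hubs. Hub rows are realizable as a single extra factor loading, which
imposes the hard bound `rho_hub < sqrt(rho_between)`; a "spoke" node
correlated ~0.5 with 89 mutually weakly-correlated partners is not a valid
correlation structure at all (the matrix loses positive definiteness), and
`cohort_spec()` rejects such requests at build time. Volumes are scaled to
per-ROI means of 3,000–10,000 mm³ with 5% coefficient of variation and sit
many standard deviations above zero, so positivity holds without
truncating the correlation structure. Covariates are injected as linear
loadings — age ~ Uniform(30, 60) years, sex ~ Bernoulli(0.5),
TIV ~ Normal(1.45×10⁶, 1.2×10⁵) mm³ — and are what `residualize()` must
remove.

A Gaussian model is sufficient on purpose: the SCN method consumes only
Pearson correlations, which the multivariate normal determines completely.
What the generator does **not** emulate: non-Gaussian volume distributions,
site or scanner effects, spatially structured measurement error, and the
empirical AAL covariance itself (`Non-goals`: no attempt to match real ROI
means). Passing tests therefore certify the estimator and inference
machinery, not any clinical claim about real cohorts.

### Reference presets

`scn_scenario()` returns three documented presets:

* **null** — `delta = 0`, no hubs, 38 vs 50 subjects (the study's group
  sizes). Used for type-I calibration: across 500 simulated cohorts with
  200 permutations each, per-density transitivity tests at
  $\alpha = 0.05$ must reject at a rate inside [0.03, 0.07], and AUC
  p-values must be approximately uniform. Calibration simulations use
  transitivity and the other four cheap core metrics; local efficiency and
  modularity cost ~25× more per permutation and are exercised in the
  end-to-end pipeline tests instead — the calibration property (exactness
  of a permutation test) does not depend on which statistic is permuted.
* **transitivity-shift** — 38 vs 50 subjects, `delta = 0.35`
  (within-module correlation 0.30 → 0.65 in group 1, `rho_between = 0.08`).
  Concentrating group 1's strongest correlations inside modules raises its
  transitivity at matched density. The effect size was chosen, once, so the
  transitivity-AUC permutation test rejects under FDR in roughly 90% of
  runs at the study's sample sizes; pilot runs showed that a still larger
  `delta` starts starving permuted pseudo-groups of positive correlations
  near $D = 0.5$, which the thresholding contract treats as an error.
* **hub-swap** — three planted global connectors per group at different
  nodes (5, 35, 65 vs 20, 50, 80), `rho_hub = 0.38`,
  `rho_between = 0.16`, `rho_within = 0.25`, 150 subjects per group. The
  exact-set mean + 2 SD recovery demanded of this preset needs correlation
  estimates precise enough that planted elevation dominates sampling noise;
  at n ≈ 40 the rule's false-positive rate makes exact recovery a coin
  flip, so this preset uses a larger simulated cohort. It demonstrates
  estimator correctness, not clinical-scale power.

## Numerical choices and edge cases

* Edge counts use round-half-away-from-zero, so $N = 90$, $D = 0.33$ gives
  exactly 1,322 edges; grid densities are generated by integer stepping
  (33:50 / 100) to avoid floating-point drift.
* Ties at the density boundary break lexicographically on the ROI index
  pair — deterministic across platforms, and it makes edge sets nested in
  density.
* Only positive correlations can become edges under density thresholding;
  requesting more edges than there are positive entries is an error, not a
  silent fill.
* Local clustering and local efficiency are 0 for nodes of degree < 2;
  transitivity is 0 when the graph has no connected triples; assortativity
  is undefined (NA) on degree-regular graphs.
* A zero-variance ROI residual vector, a non-positive volume, more than two
  group labels, or any missing cell is a hard, named error — nothing is
  imputed.
* All stage seeds fan out deterministically from one master seed; two runs
  of `scn_run()` from the same config are byte-identical (tested).

## Known limitations

* The "targeted beats random attack" intuition holds for graphs with degree
  heterogeneity. On degree-regular graphs (ring lattices) every node ties,
  the deterministic tie-break removes near-contiguous runs, and random
  failure actually fragments the graph faster — so the package asserts that
  dominance only where hubs exist.
* Betweenness-based hub identification with the mean + 2 SD rule is
  unstable at n ≈ 40 subjects for 90 nodes; hub sets from cohorts of that
  size should be read as descriptive, not inferential.
* Nodal permutation tests at 1,000 permutations cannot yield p below
  ~0.001, and with 90-node FDR families that resolution limits how small a
  nodal effect can survive correction.
* Group comparisons share one pooled residualization; if covariate effects
  truly differ by group, that choice biases both groups' networks toward a
  common covariate geometry.

## A worked run

```{r, eval = FALSE}
cfg <- scn_config(scenario = "transitivity-shift", n_perm = 1000, seed = 1)
report <- scn_run(cfg)
report$auc                 # per-group AUCs of every global metric
tidy(report$inference)     # observed differences, p, FDR flags
report$hubs                # per-group hub sets
autoplot(report$curves)    # metric curves across the density grid
write_report(report, "scn_out")
```

The same analysis runs from a shell via the bundled entry point:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "scn.R", package = "scnet"))') \
  --scenario transitivity-shift --nperm 1000 --seed 1 --out scn_out
```
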