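---
title: "Inter-region differential correlation: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-region differential correlation: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(InterDC)
```

## The question and the statistic

Bulk transcriptomes sampled from two tissue regions of the same individuals
let us ask whether the *coupling* between a gene in region 1 and a gene in
region 2 changes with disease, independently of whether either gene changes
its own expression level. InterDC formalizes this as inter-region
differential correlation (DC): for each cross-region gene pair, the Spearman
correlation is computed separately in the control (CTL) and disease (AD)
groups, and the two coefficients are compared with the Fisher r-to-z
difference test

$$
Z \;=\; \frac{\operatorname{atanh}(\rho_{AD}) - \operatorname{atanh}(\rho_{CTL})}
{\sqrt{\tfrac{1}{n_{AD}-3} + \tfrac{1}{n_{CTL}-3}}},
$$

with a two-sided standard-normal p-value. The orientation is fixed
AD-minus-CTL, so a positive $Z$ always means the pair's correlation
increased in disease.

Testing all cross-region pairs for DC directly would spend the multiple-
testing budget on pairs that are uncorrelated in both groups and cannot be
interpreted as rewiring. The pipeline therefore first builds the
**correlated-pair universe**: within each group, correlation p-values (from
the $t$ approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$) are BH-adjusted
across the full pair grid, and a pair counts as *correlated* in a group when
both $q \le 0.01$ **and** $|\rho| \ge 0.4$ (a moderate-strength gate; both
criteria are required). The universe is the union of pairs correlated in
either group, and only these are tested for DC, with BH correction applied
within the universe and edges reported at DC FDR 1%.

Each significant edge is classified by the *dominant side* — the group with
the larger $|\rho|$. AD-dominant edges **gained** correlation: `PG`
(positive gain) if $\rho_{AD} > 0$, `NG` (negative gain) otherwise.
CTL-dominant edges **lost** correlation: `LC_pos` or `LC_neg` by the sign of
$\rho_{CTL}$, pooled into the class `LC`. The dominant-side rule is the
package's deterministic reading of the four clusters such scatter plots
produce; no additional z-score threshold is imposed beyond DC significance
itself. The **dysregulation percentage** of a region pair is
$100 \times \text{(DC edges)} / \text{(universe size)}$.

## Group assignment and pairing

Individuals are assigned from CERAD scores: 1 = control, 2 = definite AD;
scores 3 (probable) and 4 (possible) are excluded. Pairing two regions keeps
only individuals profiled in both regions with group CTL or AD, aligning
columns by individual; if an individual has several samples in one region,
the first by sample id is kept with a warning (duplicate handling is a
package decision — there is no field-standard rule). Expression is assumed
already normalized to a continuous log-like scale; `residualize_covariates()`
provides generic per-gene OLS adjustment (numeric covariates mean-imputed,
categoricals one-hot with the reference level dropped, collinear columns
dropped with a warning). Residuals are returned plus the gene mean, so the
transform preserves means and is idempotent.

## Cell-type correction

Bulk correlations between regions can be driven entirely by shared
cell-composition variation rather than cell-intrinsic co-regulation.
InterDC estimates one surrogate proportion variable (SPV) per major cell
type from marker genes: candidate markers are first filtered by a one-way
F-test against the group label (default `alpha = 0.05`), keeping only
markers *not* associated with disease so the SPV cannot absorb disease
signal; the surviving markers are z-scored per gene and the leading right
singular vector of that submatrix is the SPV (unit norm, sign oriented so
its mean correlation with the markers is positive). Expression is then
residualized on all SPVs.

This is a deliberate simplification of iterative mixed-mode surrogate
estimation used by reference-free deconvolution tools: the downstream
contract — a per-cell-type, group-uncontaminated score tracking relative
abundance — is what DC correctness requires, and a single SVD per cell type
satisfies it transparently. SPVs are relative scores, not absolute cell
fractions. The default of 20 markers per type for four major brain cell
types (neurons, astrocytes, microglia, oligodendrocytes) follows the
best-performing marker-budget reported for this class of estimator;
`select_marker_model()` re-derives the budget when ground-truth proportions
(e.g. immunohistochemistry) are available, with ties going to the smaller
size.

## Downstream network analyses

- **Wilcoxon DE and DE-driven edges.** Per-gene rank-sum tests with BH
  flags at FDR 0.05/0.1/0.2; an edge is *DE-driven* when either gene is DE
  in its own region. This separates correlation rewiring from plain
  expression shifts.
- **Degrees and hubs.** Per-side partner counts; hubs are reported as a
  ranked table (top 20 by default) rather than through a hard degree
  cutoff, because no principled cutoff exists. Biotype filtering to
  protein-coding genes is supported via a two-column map.
- **Region exclusivity.** DC genes a focal region uses across several
  comparisons are pooled; the shared fraction is the proportion appearing
  in at least two comparisons.
- **Intra-region projection.** Inter-region DC pairs are re-tested within
  one region with the same gate/test/BH machinery, the BH family being the
  projected pair list only — the honest way to ask whether inter-region
  rewiring is just within-region rewiring seen twice, without the crushing
  multiple-testing burden of all within-region pairs.
- **Bipartite modules.** The DC network is clustered with the Louvain
  heuristic under standard Newman modularity (the bipartite structure is
  not encoded in the objective, matching common practice with general-graph
  Louvain routines; a $|z|$-weighted mode exists behind a flag). Module ids
  are deterministic given the seed: relabeled by descending size, ties by
  smallest member node. Reported modularity is always recomputed from the
  partition with the closed form $\sum_c [e_c/m - (d_c/2m)^2]$. Only
  modules with at least 20 genes (both sides combined) feed enrichment.
- **ORA.** One-sided (upper-tail) hypergeometric tests of each module side
  against gene-set collections, background = the region's correlated gene
  list, BH across all (module side × set) tests in a collection at FDR 5%.
  The permutation null re-assigns the real module-id structure to genes
  sampled from the background (10 permutations by default), preserving the
  module-size multiset per side exactly; the empirical FDR is the mean
  random call count divided by the real call count. Redundancy reduction of
  enriched terms (affinity propagation, set cover) is presentation-layer
  and out of scope.

## The synthetic-data generator

`simulation_config()` describes a paired two-region cohort whose defaults
mirror a large post-mortem brain study: 372 CTL and 264 AD individuals
(plus 20 CERAD-3/4 individuals that exercise the exclusion path), four cell
types with 20 markers each, continuous covariates (age, RIN), and planted
cross-region structure. Bulk expression of a gene is latent cell-intrinsic
signal plus $\sum_c \text{proportion}_c \times \text{loading}_c$ plus
covariate effects plus Gaussian noise.

Design choices, fixed once:

- **Planted correlations via shared latent factors.** A pair targeting
  Spearman $\rho$ is generated from a bivariate normal with Pearson
  $r = 2\sin(\pi\rho/6)$, the exact inverse of
  $\rho_S = (6/\pi)\operatorname{asin}(r/2)$, making planted rank
  correlations analytically controllable. Planted genes are emitted on a
  unit-variance latent scale free of composition and covariate effects, so
  their empirical $\rho$ converges to the target. Planted *blocks* share
  one factor per group across all member genes, creating whole bipartite
  modules that gain or lose correlation together (the structure Louvain
  should recover).
- **Composition confounding by concentration, not mean.** Proportions are
  Dirichlet with mean (0.40, 0.30, 0.15, 0.15) and concentration 50 in CTL
  vs 10 in AD. Equal means keep marker genes clear of the robust-marker
  F-test; the larger AD variance makes genes loading on the same cell type
  gain correlation in AD *purely through composition* — false DC edges of
  roughly $L^2\sigma_p^2/(L^2\sigma_p^2+\sigma^2)$, about 0.6 at the
  default marker loading 5 and noise SD 0.5, versus about 0.3 in CTL.
  These numbers come from that variance arithmetic, chosen so the
  confound straddles the 0.4 gate and cell-type correction has something
  real to remove.
- **Markers load 5× other genes** on their own type (loading 5 vs 1 for
  the weakly composition-influenced genes), giving SPV-truth Spearman
  correlations above 0.9 at these sample sizes.
- **Default planted classes**: 50 edges each of PG (0 → 0.7),
  NG (0 → −0.7) and LC (0.7 → 0), 50 stable pairs at 0.6 in both groups
  (in the universe, not DC), and two 15+15-gene blocks gaining 0.6. The
  0.7/0.6 magnitudes are chosen for testability at desk-scale cohorts,
  not as estimates of real effect-size distributions, which the source
  data do not constrain.

What the generator does *not* emulate: count-level sampling and library
size (inputs are declared normalized), more than two regions per dataset
(multi-region studies compose several paired datasets), heavy-tailed
expression, and spatially structured composition. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to every property of real RNA-seq.

## Numerical and procedural choices

- Spearman p-values use the t-approximation for all $n \ge 4$; exact
  permutation p-values are unnecessary at the sample sizes in scope, and
  the DC statistic has its own closed-form oracle in the test suite.
- Zero-variance genes are excluded from the pair grid (with a logged
  count); $|\rho| = 1$ is clamped to $1 - 10^{-12}$ before `atanh` with a
  warning; group sizes must exceed 3 for the DC test.
- Pair enumeration is blocked (`block_size` genes per block) so working
  matrices stay at $O(\text{block}^2)$; each block is an independent
  `cor()` call, so the edge list is bit-identical for every block size.
- BH families: correlation p-values per (group × region pair) over the
  full grid; DC p-values within the region pair's universe; ORA within a
  collection; the intra-region projection within its projected list.
- Marker-model selection rounds correlations to 9 decimals before the
  argmax so numerically tied models resolve to the smaller marker budget.
- All randomness (generator, Louvain node order, permutation null) is
  seeded; pipeline artifacts embed the resolved configuration, and re-runs
  with the same seed are byte-identical.

## Known limitations

- The Fisher z standard error $1/(n-3)$ is exact for Pearson correlations
  of bivariate normal data; for Spearman coefficients the asymptotic
  variance is larger by roughly $(1+\rho^2/2)$, so the DC test grows
  mildly anticonservative as the null correlation strengthens. At the
  defaults (moderate correlations, FDR 1%) the realized false-discovery
  proportion stays within the tolerated band of the test suite, but users
  testing universes dominated by very strong stable correlations should
  expect some inflation. This mirrors the common practice of applying
  `r.test`-style machinery to Spearman estimates.
- Selecting the universe and testing DC on the same data induces mild
  selection effects for pairs near the 0.4 gate.
- Louvain is a heuristic: modularity values are reproducible under a seed
  but not guaranteed optimal; stability across seeds is part of the test
  suite rather than a theorem.
- SPVs capture the leading composition axis per cell type; closely
  collinear cell types or markers shared across types (disallowed within
  one model) would degrade separation.

## Problem sizes used in validation

The test suite and the acceptance script run the statistics at desk scale:
cohorts of 60–500 individuals per group, 100–400 genes per region, 20
replicates for the null false-discovery estimate, 10 seeds for partition
stability, 10 permutations for the enrichment null, and the full default
pipeline (372 + 264 individuals, 400 genes per region). These sizes were
chosen so every property is estimated with useful precision while a full
validation run completes in about a minute.
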