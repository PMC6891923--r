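---
title: "Methods: circular cell-cycle trajectories from single-cell Hi-C"
author: "circlet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular cell-cycle trajectories from single-cell Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell Hi-C yields one sparse genome-wide contact map per cell. As a
cell traverses the cell cycle its chromatin reorganizes continuously —
short-range contacts (200 kb–2 Mb) build up through S phase, very long-range
contacts recede, and mitotic chromosomes show a characteristic contact band
at 2–12 Mb separations. Because the process is cyclic, ordering cells by
these signatures is a *circular* pseudotime problem: there is no natural
starting cell, no endpoints, and any solution is only defined up to rotation
and reflection of the circle. `circlet()` estimates this circular ordering
from multiscale contact features, and the surrounding functions score it
against FACS phase labels, divide it into substages, and track insulation
boundaries and chromatin loops along it.

## Feature sets

Four per-cell feature sets summarize a binned intrachromosomal contact map
(all are intrachromosomal; interchromosomal records are dropped at input):

* **CDD** — contact probabilities over log2-spaced genomic-distance bins.
  A contact at distance $d$ (bp) falls in bin
  $\mathrm{loc} = \lfloor (\log_2 d + s)/s \rfloor$ for each exponent step
  $s \in \{0.1, 0.125, 0.2, 0.33\}$; per-step counts are normalized to sum
  to 1 so sequencing depth cancels. Only $d > 20$ kb contributes. Two
  renderings of the log-binning rule are in circulation, so the
  alternative $\lfloor \log_2 d / s\rfloor$ is available behind
  `variant = "plain"`; both give log-spaced bins and identical downstream
  behavior.
* **PCC** — per-pair contact coverage. The significance of bin pair
  $(i,j)$ is its mean count over all $K$ cells,
  $\mathrm{value}(A_{ij}) = \sum_k A_{ij}^{(k)}/K$; pairs above the 0.99
  quantile of these values ("top 1%") become feature columns, holding each
  cell's count there divided by its total contact count. The across-cell
  variance is computed and available as an alternative selector
  (`selector = "variance"`).
* **Ins** — per-bin insulation,
  $\mathrm{Ins}(b) = \sum_{i,j \in [b\pm s]} A_{ij} \big/
  \sum_{i \le b \le j} A_{ij}$ with window half-width `scale`. The
  numerator is a square window, the denominator the contacts bridging bin
  $b$; insulating bins score high. Bins whose across-cell mean (or
  variance) exceeds the 0.90 quantile are kept as features.
* **MCM** — composite per-cell metrics: % contacts below 2 Mb, % in the
  mitotic 2–12 Mb band, mean distance of far contacts (> 4.5 Mb), and —
  when a replication-timing annotation is supplied — the early-replicating
  fraction of fragment ends. Without the annotation the vector degrades to
  three entries rather than failing, since replication timing is external
  to Hi-C. Cells without far contacts get the 4.5 Mb floor (with a
  warning) to avoid propagating missing values into the embedding.

The default combination assembled by `extract_features()` is
MCM + PCC + CDD — one global-structure set plus two local-interaction
sets; columns are standardized to zero mean and unit variance and
constant columns dropped.

## The estimator

`circlet()` proceeds in six steps.

1. **Diffusion embedding.** The feature matrix is reduced to `M = 15`
   diffusion components: an adaptive Gaussian kernel (bandwidth = distance
   to the `kernel_k = 15`-th neighbor) on the union-symmetrized
   neighborhood graph, row-normalized to a Markov matrix and
   eigendecomposed; the trivial constant eigenvector is dropped and
   components are scaled by their eigenvalues.
2. **kNN graph.** Cells are joined to their `k = 25` nearest neighbors in
   the embedding (union symmetrization), edges weighted by Euclidean
   distance. A disconnected graph is an error rather than being silently
   restricted to its giant component — a circular ordering of a fragment
   would be meaningless.
3. **Waypoints and initial ordering.** `W = min(150, N/4)` waypoint cells
   are spread over the embedding by stratified rank sampling per component,
   each candidate replaced by the medoid of its 10-cell neighborhood (a
   median filter that keeps outliers from being chosen). One waypoint `s`
   is drawn uniformly as the starting cell; the initial position of cell
   $i$ is its Dijkstra shortest-path distance, $\tau_i^{(0)} = D_{s,i}$.
4. **Perspectives and disagreement.** Each waypoint $w$ estimates every
   cell's position as
   $P_{w,i} = \tau_w + D_{w,i}$ if $\tau_i > \tau_w$, else
   $\tau_w - D_{w,i}$. For waypoint pairs,
   $Q_{w_i,w_j} = P_{w_i,w_j} - \tau_{w_j}$ is near zero when both lie on
   the same semicircle around `s` and large in magnitude otherwise.
   Working through the branch cases shows the sign of the large entries is
   data-dependent ($+2\tau_{w_i}$ for paths through `s`,
   $-2\tau_{w_j}$ for paths around the far pole), so the two-block
   structure lives in $|Q|$: waypoints are split into the two semicircles
   by average-linkage hierarchical clustering of
   $1 - \mathrm{cor}(\text{rows of } |Q|)$, cut at two clusters. The
   starting cell's row is identically zero and is excluded; it and all
   non-waypoint cells join the semicircle of their nearest waypoint (ties
   toward semicircle 1). A cluster with fewer than two waypoints triggers
   a waypoint re-draw (up to `retries = 5`).
5. **Refinement.** Within each semicircle, cell positions are re-estimated
   as Gaussian-weighted averages of the semicircle's waypoint
   perspectives, $\tau_i = \sum_w P_{w,i} W_{w,i}$ with
   $W_{w,i} \propto \exp(-(D_{w,i}/\sigma)^2)$ and $\sigma$ the standard
   deviation of the semicircle's distance block — closer waypoints vote
   more. The weights are normalized per cell over waypoints so each
   estimate is a true weighted average; the printed formula of the source
   method normalizes over cells instead, which does not yield a weighted
   average, and that literal variant is kept behind
   `weight_norm = "cells"`.
6. **Iteration, merge, normalization.** Steps 4–5 repeat, carrying the
   signed merged trajectory $[-\tau_{S1}, \tau_{S2}]$, until the Pearson
   correlation of successive iterates exceeds 0.9999 (at most
   `max_iter = 50` iterations; non-convergence returns the last iterate
   with a warning and flag). The final vector is min–max normalized to
   $[0,1]$. The alternative merge $[\tau_{S1}, -\tau_{S2}]$ is its exact
   reflection and defines the same circular ordering; `merge_variants()`
   exposes both for verification.

All randomness (waypoint draw, starting cell) flows from one integer seed
recorded in the fit, so runs are reproducible; different seeds agree up to
rotation and reflection of the circle, which is all a circular ordering
determines.

## Evaluation

* **LCS** counts label changes between adjacent FACS-labeled cells along
  the circular ordering (wrap-around included, unlabeled cells skipped):
  $\mathrm{LCS} = 1 - (s_c - 4)/(N - 4)$, clamped to $[0,1]$. Four
  contiguous phase arcs give exactly 1; fully alternating labels give 0.
* **Successive-phase AUC** takes one phase as positive and its successor
  as negative. The circle must be linearized first: positions are rotated
  so the pair's labeled cells span a contiguous arc, with the cut placed
  in the largest gap between the pair's cells. The AUC is then the rank
  statistic $P(\tau_+ < \tau_-) + \tfrac12 P(\text{tie})$, which equals a
  threshold-sweep ROC area (tested as an oracle equivalence). Because the
  fit's direction is arbitrary, `evaluate_trajectory()` scores the
  orientation (tau vs 1 − tau) with the larger summed AUC; a
  `symmetric` flag reports max(AUC, 1 − AUC) per pair instead.
* **Robustness** re-runs feature extraction and fitting after deleting a
  fraction of cells or filling in duplicates whose contacts are
  multinomially resampled, and reports circular rank correlations against
  the surviving cells' true angles.

Circular agreement is measured with the pairwise Fisher–Lee circular
correlation on rank angles, $\sum_{i,j}\sin(a_i-a_j)\sin(b_i-b_j)$
normalized by the marginal sums. The circular-mean form of this
coefficient is degenerate when angles are uniformly spread — exactly the
case for rank angles — which is why the pairwise form is used.

## Substages and structure dynamics

`divide_stages()` cuts the circle where the smoothed (11-cell circular
moving average) Euclidean distance between trajectory-adjacent cells in the
top three diffusion components peaks; peaks are ranked by prominence, an
explicit rule standing in for visual inspection, and can be overridden or
supplemented with manual `split_spec` cut positions (the wrap point
$\tau = 0$ counts as one implicit cut). The canonical 12 substages
(Post-M, G1-1, G1-2, G1–ES, ES, ES–MS, MS-1, MS-2, MS–LS, LS–G2, G2,
Pre-M) are anchored by majority FACS label when labels exist, else by
placing Pre-M at the arc whose pooled map is richest in 2–12 Mb contacts.
`merge_stages()` maps them onto the five larger stages (G1 = G1-1 + G1-2,
ES, MS = MS-1 + MS-2, MS–G2 = MS–LS + LS–G2, G2), leaving transition arcs
unassigned.

For structure dynamics: per-stage pooled maps are scored with the
insulation formula above; boundary candidates are *local maxima* of that
score (with the square-over-cross ratio, insulating bins score high — the
opposite sign convention from log-ratio insulation tracks), kept above the
0.90 quantile of scores pooled across all substages (one uniform
threshold). Boundaries from different stages within one bin of each other
merge, capped at `n_stages × bin_width`, score = max; presence in all
stages makes a boundary `common`, in exactly one `specific:<stage>`.
Aggregate peak analysis averages 13 × 13-bin (325 kb at 25 kb resolution)
submatrices centered on loops in the upper triangle; enrichment is the
central pixel over the lower-left ⌊pad/2⌋-square corner block (balanced
maps) or over all four corner blocks (observed/expected maps), and two
loop sets are compared by a Wilcoxon rank-sum test on their central-to-
corner ratio vectors. Matrix balancing is plain iterative proportional
fitting (tolerance 1e-6, max 200 iterations) — plumbing sufficient for
APA, not a full Knight–Ruiz implementation. Feature enrichment of
boundaries or anchors is observed overlap counts over the mean of seeded
random same-size, same-chromosome placements.

## The synthetic generator

`simulate_schic()` provides seeded datasets with known circular ground
truth so the whole pipeline is testable offline. Cells sit at sorted
uniform angles; each draws a negative-binomial number of contacts
(mean 5000, size 20) whose distances come from a three-band log-uniform
mixture — short 200 kb–2 Mb, mitotic 2–12 Mb, long 5–25 Mb — with smooth
raised-cosine weights peaking at different angles (mitotic at the M-phase
point, long-range in G1, short-range in S/G2) so the weight curve is an
injective closed loop and the angle is identifiable from contact structure
alone. Planted boundaries deplete spanning short-range contacts and
planted loop anchors receive focal contacts, both with cyclic intensity,
giving the Ins and PCC features real signal. Four contiguous phase-label
arcs cover fractions (0.24, 0.26, 0.22, 0.28) of the circle, realistic
FACS label proportions for a cycling mESC population. Default problem
sizes (400 cells, two 50 Mb chromosomes, 500 kb bins) give clear signal at
desk scale.

What the generator does *not* emulate: genome-wide chromosome counts and
realistic contact depths (~127k pairs/cell in real data), distance-decay
within bands (log-uniform, not power-law), compartmentalization,
replication-timing structure, and dropout correlated with genomic
features. Passing recovery tests therefore demonstrates that the estimator
correctly inverts the generative circular structure it is given — not that
any particular real dataset will reach the same scores.

## Numerical choices and limitations

Degenerate inputs are handled explicitly: zero insulation denominators and
non-interior bins are `NA` (flagged, not errors); a single-waypoint
semicircle falls back to that waypoint's perspective row; a zero distance
spread makes refinement an unweighted mean; duplicate embedding points get
identical coordinates. Ties in nearest-waypoint assignment resolve toward
semicircle 1, making fits deterministic given the seed.

Known limitations: the method assumes one cycle — branching trajectories
and multiple disjoint cycles are out of scope; very sparse cells can make
the kNN graph disconnected (raised as an error advising larger `k`); the
number of diffusion components, `k`, and `W` interact with data density
and may need adjustment far from the default scale; and the kernel
bandwidth rule and the waypoint median-filter neighborhood are points
where reasonable implementations differ, so both are documented explicit
choices here.
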