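# circlet

Circular cell-cycle trajectory reconstruction from single-cell Hi-C
contact maps.

## What it does, and for whom

Single-cell Hi-C assigns each cell one sparse map of chromosomal contact
frequencies. Chromatin architecture reorganizes continuously through the
cell cycle — short-range contacts (200 kb–2 Mb) accumulate through S
phase, long-range contacts (> 5 Mb) recede, and mitotic chromosomes show a
distinctive contact band at 2–12 Mb — so a cell's contact map encodes its
cell-cycle position. `circlet` is for chromatin biologists and
computational genomicists who want to order hundreds of single cells along
this cycle *without specifying a starting cell*, then study how TAD
boundaries, insulation strength and chromatin loops change along the
reconstructed trajectory.

## The estimator

Each cell is summarized by multiscale contact features: contact-distance
distributions over log2-spaced bins (CDD, with
`loc = floor((log2 d + s)/s)` for steps s ∈ {0.1, 0.125, 0.2, 0.33}),
significant bin-pair coverage (PCC: pairs whose across-cell mean count
`value(A_ij) = Σ_k A_ij^(k)/K` exceeds the 0.99 quantile), per-bin
insulation scores (`Ins(b)` = square-window over cross-window contact
sums), and composite metrics (MCM: % near, % mitotic-band contacts, mean
far-contact distance, early-replicating fraction). The default
combination is MCM + PCC + CDD.

Cells are embedded with diffusion maps and joined into a k-nearest-
neighbor graph with Euclidean edge weights. From a randomly chosen
starting waypoint `s`, the initial position of cell *i* is the Dijkstra
shortest-path distance `τ_i(0) = D_s,i`. Each waypoint *w* then estimates
every cell's position (the perspective matrix)

    P[w,i] = τ_w + D[w,i]   if τ_i > τ_w
             τ_w − D[w,i]   otherwise

and the waypoint–pair disagreement `Q[wi,wj] = P[wi,wj] − τ_wj` — near
zero for same-semicircle pairs, large for opposite ones — is clustered to
split the circle into two semicircles around `s`. Each semicircle's
ordering is refined by Gaussian-weighted waypoint voting
(`τ_i = Σ_w P[w,i]·W[w,i]`, weights `exp(−(D/σ)²)` normalized per cell),
and the split/refine steps iterate until successive orderings correlate
above 0.9999. The merged trajectory `[−τ_S1, τ_S2]` is normalized to
[0, 1]; its alternative merge is the same circular ordering reflected.

Downstream, the trajectory is scored against FACS phase labels (label
change score `LCS = 1 − (s_c − 4)/(N − 4)` and AUCs between successive
phases), divided into the 12 canonical substages, and used to track
per-stage insulation boundaries (common vs stage-specific) and aggregate
loop enrichment (APA, 325 kb windows).

A seeded synthetic generator (`simulate_schic()`) produces single-cell
Hi-C datasets with known circular ground truth — cyclic distance-band
mixtures, planted boundaries and loops, contiguous phase-label arcs — so
the entire pipeline is testable offline.

## Worked example

```r
library(circlet)

sim      <- simulate_schic(sim_spec(seed = 7))      # 400 cells, known angles
features <- extract_features(sim$cells)             # MCM + PCC + CDD
fit      <- circlet(features, seed = 7)
fit
#> Circular trajectory fit (circlet)
#>   cells:       400
#>   waypoints:  100 (start: cell0010)
#>   iterations: 2 (converged)
#>   semicircles: 200 / 200 cells

labels <- setNames(sim$truth$phase, sim$truth$cell_id)
evaluate_trajectory(fit, labels)
#> Trajectory evaluation
#>      LCS    G1-ES    ES-MS MS-LS/G2 LS/G2-G1
#>   0.9747   0.9993   0.9993   0.9996   0.9998

theta <- setNames(sim$truth$theta, sim$truth$cell_id)
circular_rank_cor(fit$tau, theta[fit$cell_ids])
#> [1] 0.994
```

`fit$tau` holds each cell's circular pseudotime in [0, 1]. The evaluation
prints the five scores: the LCS (0.97 here — labels change barely more
often than the unavoidable four junctions) and the four successive-phase
AUCs (≈1: each phase almost perfectly precedes its successor). The
circular rank correlation of 0.994 says the recovered ordering matches
the planted angles nearly exactly, up to the rotation and reflection a
circle cannot determine. `divide_stages(fit$embedding, fit, labels =
labels)` then partitions the circle into the 12 substages, and
`pool_stage_maps()`, `call_boundaries()`, `apa()` etc. analyze chromatin
structure along it.

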