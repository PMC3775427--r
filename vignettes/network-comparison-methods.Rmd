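---
title: "Comparing task coactivation and resting-state network configurations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing task coactivation and resting-state network configurations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netshift)
```

## The scientific question

Functional brain networks can be estimated in two very different ways. A
*meta-analytic coactivation network* asks, across thousands of published
task studies, how often two brain regions are reported active together. A
*resting-state network* correlates spontaneous BOLD fluctuations between
the same regions in task-free scans. Edge weights from the two sources are
strongly correlated — regions that coactivate under task also covary at
rest — yet the *configuration* of the two graphs can still differ: how
efficiently the whole network integrates information, how locally clustered
it is, how cleanly it decomposes into modules, and which nodes act as hubs.

`netshift` implements the full comparison pipeline: build both weighted
matrices over a shared set of spherical regions of interest (ROIs),
binarize them at matched sparsity, compute binary graph metrics with random
references, and test configuration differences with an edge-exchange
permutation null and a sorted degree-difference envelope.

## The two builders

### Coactivation matrix

Input is a nonnegative seed-by-target value matrix: row *i* holds the
coactivation values of seed ROI *i* with every target ROI (extracted from
that seed's whole-brain map by averaging voxel values within each 10 mm
sphere, or supplied directly). Three deterministic steps give the
connectivity matrix:

1. **Diagonal normalization** — each seed inquiry returns a different
   number of studies, so row *i* is divided by its own diagonal entry,
   making the diagonal exactly 1 and removing per-seed scale. The built
   matrix is therefore invariant to rescaling any raw row by a positive
   constant; the packaged tests assert this at a relative tolerance of
   1e-12, which is the floating-point image of an identity that holds
   exactly in real arithmetic.
2. **Add-one log transform** — raw values are strongly right-skewed;
   `log1p` pulls them toward normal. The natural log is used; since any
   log base is a monotone rescaling, edge *ranking* — and hence every
   thresholded binary graph downstream — does not depend on the base.
3. **Symmetrization** — coactivation of A with B and of B with A are
   similar but not identical; averaging the matrix with its transpose
   defines the undirected weight. Every diagonal entry of the result is
   `ln 2` (1 after normalization, then `ln(1 + 1)`).

Where sphere extraction is used, a voxel belongs to an ROI when its world
(MNI mm) center lies within the sphere radius (closed ball), and the
in-sphere *mean* is the default statistic. The source maps do not state
mean versus peak; the mean matches common ROI practice and is robust to
single-voxel noise, and the statistic is configurable (`"max"`,
`"center"`).

### Resting-state matrix

Per subject: ROI time series (T frames at TR seconds) are cleaned by
ordinary least-squares regression of a 23-column nuisance design — six head
motion parameters, their backward-difference derivatives (first row 0; any
constant offset of the convention is absorbed by the intercept), five white
matter and five cerebrospinal fluid eigenvector time series, and an
intercept — then band-pass filtered to 0.01–0.1 Hz, the conventional
resting fluctuation band. Subjects whose peak absolute translation exceeds
3 mm (strictly) are excluded beforehand; rotations are logged but not
thresholded, because the criterion is in millimetres. Kendall's tau-b
between all ROI pairs gives the subject matrix (rank-based, damping noise
spikes; tau-b is tie-corrected — tie handling was not specified upstream,
and tau-b is the standard choice). Group pooling transforms off-diagonal
entries with Fisher's z (`atanh`), averages across subjects, and transforms
back; the diagonal is set to 1 untransformed since `atanh(1)` is infinite,
and correlations of exactly ±1 are clipped to 1 − 1e-7 with a warning.

Two orders of regression and filtering are defensible; the package
regresses first (the conventional listing order) and exposes
`filter_first = TRUE`. The default filter is an ideal FFT mask — bins with
`low_hz ≤ f ≤ high_hz` (inclusive) are kept, everything else including DC
is zeroed — chosen because its pass/stop behaviour is exactly testable; a
4th-order zero-phase Butterworth (via the `signal` package) is available
when smoother roll-off matters. Applying Fisher's z to Kendall's tau
follows the pipeline being reproduced; z is conventionally paired with
Pearson's r, and this choice is deliberate, not an endorsement.

## Matched-sparsity binarization and graph metrics

Because coactivation values and rank correlations live on different
scales, the two weighted matrices are compared only after thresholding at
*matched sparsity*: exactly `round(s · n(n−1)/2)` strongest edges are kept
in each (rounding half away from zero; weight ties at the boundary break
by lexicographic pair order so the edge set is deterministic and
seed-free). The sweep grid defaults to 6–40 % in 1 % steps (35 points), the
range in which large-scale brain networks behave as small-world networks.

On the resulting binary undirected graphs the package computes, from
scratch (with igraph used only as an independent cross-check in the test
suite):

- **Global efficiency**: mean inverse shortest-path length over ordered
  pairs, 0 for disconnected pairs; BFS path lengths are computed in C++.
- **Mean clustering coefficient**: `C_i = 2 t_i / (k_i (k_i − 1))`, 0 when
  `k_i < 2`, averaged over all nodes.
- **Modularity (Newman's Q)** of the best partition found by a Louvain
  optimizer (greedy local moves plus graph aggregation). The Q landscape
  is degenerate, so the optimizer restarts from shuffled node orders
  (default 10) and keeps the best partition; the reported `q` is
  recomputed on the original graph, so it is exact for the returned
  assignment. Q for disconnected graphs is evaluated on the full graph,
  per the formula. Module ids are contiguous from 1.

Random references average the three metrics over (by default 1000) uniform
G(n, m) graphs at the same node and edge count; "random network" is
ambiguous between G(n, m) and degree-preserving rewiring, so Maslov–Sneppen
rewiring (10 swaps per edge) is provided as an option, with G(n, m) the
default.

## The edge-exchange permutation null

At a given sparsity both graphs carry the same edge count *m*. The null
model scrambles only what distinguishes them: let D₁ and D₂ be the edges
private to each graph (|D₁| = |D₂|); draw a random half of each
(`round(frac · |D|)`, half rounded up) and swap the two selections. This
preserves each graph's edge count, their intersection and their union in
every draw — so the matched-sparsity contract survives permutation, which
is also why "exchange 50 % of the different edges" is implemented as
swapping equally sized subsets rather than independently reassigning each
edge (the latter can violate the contract and is rejected). The p-value is
the add-one estimator `p = (1 + #{|null| ≥ |obs|}) / (1 + n_perm)`,
two-sided by default (differences in both directions are of interest;
one-sided available), never exactly zero at finite `n_perm`. With the
reference 1000 permutations the smallest attainable p is 1/1001, which is
exactly what makes a `p < 0.001` criterion meaningful at that scale. Each
permutation (and each Louvain call inside it) draws its seed from a root
seed by counter, so sweeps are reproducible cell by cell.

For hub structure, degrees of the two graphs are correlated across
sparsity (Pearson by default — degree scatter is summarized by linear
fits — Spearman by flag), and per-node degree differences are sorted into a
curve whose permutation envelope (per-rank min/max over scrambled pairs,
plus a two-sided 0.1 % percentile band) flags ranks where the observed
curve leaves the null band. Exceedance is judged per rank position, not
per node identity, because sorted curves are compared. "Least degree
differences" means most negative, not smallest magnitude. Tables of the
top-k and bottom-k nodes, with MNI coordinates when an ROI table is
supplied, summarize the shifts.

## The synthetic-data generator

The generator exists so the whole pipeline is testable without imaging
data; its defaults are the package's study conditions.

- `gen_modular_matrix()`: symmetric weights, Gaussian around `mu_in`
  within planted modules and `mu_out` between, clipped at 0 (the simplest
  nonnegative emulation of z-like values), diagonal 1, ground-truth module
  labels attached. Defaults 60 nodes, 4 modules of 15, `mu_in = 0.6`,
  `mu_out = 0.2`, `sigma = 0.05` — a block contrast strong enough to be
  recovered yet noisy enough that thresholding is nontrivial.
- `gen_seed_count_matrix()`: multiplies each row by a per-seed scale
  (emulating inquiries that return different study counts) and adds
  half-normal noise off-diagonal; with zero noise, the coactivation
  builder recovers the symmetrized log of the base exactly.
- `gen_subject_panel()`: per subject, T×N series with the template as
  population covariance (templates that are slightly indefinite are
  repaired by clipping eigenvalues at 1e-10, with a warning), i.i.d.
  measurement noise, random-walk motion traces, and smoothed-noise WM/CSF
  regressors. One subject can be planted as a motion violator whose peak
  translation is scaled to a chosen value (only the max-amplitude screen
  matters downstream). Per-subject seeds derive from the root seed, so
  subject k's data is stable under panel resizing. Defaults: 20 subjects,
  T = 240 at TR 1.8 s, noise SD 0.5 — a typical single-site resting
  acquisition after dummy-scan removal.
- Task-like matrices are manufactured from rest-like ones by
  `boost_between_modules()` (stronger between-system coupling → higher
  efficiency, lower Q) and `plant_hub()` (ground truth for hub-shift
  recovery).

What the generator does **not** emulate: the study-sampling process behind
coactivation databases (papers, foci, smoothing kernels), hemodynamics
(no HRF), spatial preprocessing, and the heavy-tailed, spatially
autocorrelated noise of real BOLD data. Passing tests therefore show that
the *pipeline* recovers planted structure under controlled conditions —
not that real task and rest networks differ; that inference belongs to the
data, and real degree correlations, for instance, have no dataset-free
target.

## Numerical choices and degenerate inputs

- Edge-count rounding: half away from zero, documented so counts are
  bit-stable (140 nodes at 20 % sparsity → exactly 1946 edges).
- Thresholding refuses sparsities that would keep zero edges or all pairs.
- Identical inputs to a permutation test are degenerate: observed
  difference 0, p = 1, a warning, and no exchange attempted.
- `sum(degree_a) = sum(degree_b) = 2m` at matched sparsity, so degree
  differences always sum to zero (the per-node sum is not constrained).
- All randomized functions are pure functions of an integer seed; child
  seeds are derived by a fixed linear-congruential map kept below 2^31.

## Problem sizes used by the packaged checks

The test suite exercises the pipeline at 60 nodes and below, with
permutation counts of 200 and panels of up to 20 subjects × 240 frames;
the acceptance script sweeps the full 35-point grid at 60 nodes with 200
permutations per cell (at that count the add-one p cannot reach the
reference 0.001, so its significance flag uses 0.01). These sizes were
chosen so the complete battery runs comfortably on one CPU while leaving
every algorithmic path identical to a full-size 140-node, 1000-permutation
analysis, which the same functions run unchanged.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(mode = "synthetic", seed = 1, grid = c(0.10, 0.20, 0.30),
                  n_perm = 200, alpha = 0.01)
res <- run_pipeline(cfg)
res$weight_correlation      # edge-weight similarity of the two matrices
dplyr::filter(res$tests, sparsity == 0.20)
res$hubs[[1]]$hubs$top      # planted hub should head this table
autoplot(res$tests)
```

## Known limitations

- Louvain is a greedy heuristic; different restart counts can return
  different partitions with slightly different Q on degenerate landscapes.
  Fixed seeds and restarts make any given analysis reproducible.
- Kendall's tau via `stats::cor` is O(T²) per pair; very large panels are
  the slowest stage of the resting chain.
- The ideal band-pass assumes the series is well represented by its DFT;
  for strong edge effects the Butterworth option is preferable.
- The G(n, m) reference ignores degree sequences; use the rewiring model
  when degree structure must be held fixed.
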