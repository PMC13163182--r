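---
title: "Within-subject hub disruption analysis: models, parameters and design choices"
author: "hdinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-subject hub disruption analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdinet)
```

## The problem

Longitudinal resting-state fMRI designs scan the same brain under several
states — here a baseline of rested wakefulness (RW) and two sleep-loss
states, total sleep deprivation (TSD) and chronic sleep restriction (CSR) —
and ask whether the functional network reorganizes between states. Global
summaries (efficiency, modularity) often fail to discriminate conditions,
and node-by-node testing suffers from the many-regions/few-subjects
imbalance. The hub disruption index (HDI) sits between these extremes: it is
one number per subject and comparison, but it is computed from the full
nodal profile, so it detects distributed reorganization — hubs losing
centrality while peripheral regions gain it — that both extremes miss.

`hdinet` implements the whole chain from regional time series to inference:

1. **Wavelet connectivity.** Each regional series is decomposed with the
   maximal overlap discrete wavelet transform (MODWT); interregional Pearson
   correlations of the level-3 detail coefficients estimate connectivity in
   the ~0.05–0.1 Hz band at TR = 1.25 s.
2. **Graph construction.** Each correlation matrix is binarized at a fixed
   edge budget, anchored on the minimum spanning tree (MST) of the distance
   transform `1 - |r|` so every graph is connected.
3. **Topology metrics.** Nodal: degree centrality (normalized by the
   maximum degree), local clustering, closeness. Global: efficiency, mean
   clustering, mean path length, modularity, mean between-community
   geodesic distance.
4. **Within-subject HDI.** For nodal metric `m`, the index
   `kappa` is the OLS slope of `m_i(cond) - m_i(ref)` on `m_i(ref)` across
   nodes, using the *same subject's* reference scan — not a group average —
   as regressor.
5. **Permutation validation.** Node-label shuffles, subject-pairing breaks,
   and within-subject condition swaps, plus generic paired (sign-flip) and
   unpaired comparisons.
6. **Covariate-constrained manifold learning (CCML).** An ISOMAP-style
   embedding whose first coordinate is clamped to `alpha * kappa`, with a
   centroid-distance permutation test for group separation.

Everything is exercised end to end on a synthetic cohort whose disruption
strength is implanted and therefore known.

## The synthetic cohort

The generator emulates the study design the method targets: 28 subjects
× 3 conditions (84 scans), 89 regions, 8-minute scans at TR = 1.25 s
(384 volumes).

**Covariance model.** The reference correlation matrix has a core–periphery
block structure: a fraction `hub_fraction` (default 0.15) of regions are
hubs with elevated within-hub (0.50) and hub–periphery (0.25) correlations
over a periphery level of 0.12. The HDI is only informative when the
reference degree distribution is heterogeneous, which this structure
guarantees. Three subject-level perturbations create interindividual
variability: two hub slots are swapped with periphery nodes per subject,
per-node strength factors `u_i ~ U(0.8, 1)` scale the off-diagonal, and
pairwise N(0, 0.04) jitter breaks block-level ties. The jitter matters more
than it looks: without it the thresholded graphs are near-unique
realizations of their degree sequences, and every "random" realization of a
null condition reproduces the same graph, leaving permutation nulls
degenerate. Positive definiteness is restored by flooring eigenvalues at
0.05 and renormalizing; spec-level validity (the three base levels must
form a positive-definite matrix) is checked at construction time.

**Temporal model.** AR(1)-filtered multivariate Gaussian noise,
`x_t = phi * x_(t-1) + sqrt(1 - phi^2) * e_t` with `e_t ~ N(0, Sigma)` and
`phi = 0.3` by default. This is the minimal model with realistic temporal
autocorrelation whose stationary cross-sectional covariance equals `Sigma`
exactly, so band-limited wavelet correlations estimate the generating
correlation directly. It deliberately omits physiological noise, motion,
scanner drift and spatial autocorrelation of real BOLD data — passing tests
show the *pipeline arithmetic* is right, not that the method is robust to
fMRI artifacts.

**Disruption implant.** For a non-reference condition with target slope
`kappa_t`, target degrees are `d'_i = round((1 + kappa_t) d_i + c)` with
the offset `c` chosen (by bisection, then unit redistribution over a seeded
node order) so the total edge count is preserved, values clipped to
`[1, N-1]`, parity corrected, Erdős–Gállai-checked, and realized as a
random simple connected graph. Regressing `d' - d` on `d` then recovers
`kappa_t` up to rounding noise; the package's recovery contract is
±0.1, which absorbs clipping and realization effects. For time series, the
implanted adjacency is propagated into a condition correlation matrix
(implanted edges at 0.5, the periphery level elsewhere, uniformly shrunk
until the smallest eigenvalue reaches 0.05). Uniform shrinkage is a
monotone transform of the off-diagonal, so the thresholded graph of the
condition matrix is exactly the implanted graph.

**Default `kappa_targets`** are TSD = −0.5, CSR = −0.3: mid-range
disruption strengths chosen once as plausible for a study that reports
uniformly negative within-subject kappas; no published per-condition point
value exists to copy.

**Seeds.** All randomness derives from the single spec seed through
per-subject and per-condition child streams, so any subject is
independently reproducible and two runs are bitwise identical.

## Numerical and statistical choices

**Wavelet filter and boundaries.** Least-asymmetric Daubechies length-8
("la8"), the convention of the wavelet-correlation connectivity literature;
periodic boundaries for the transform itself (the energy-partition identity
is then exact, and the test suite asserts it to 1e-8), reflection extension
for correlation estimation with the first `(2^j - 1)(L - 1)`
boundary-affected coefficients excluded — the unbiased-estimator
convention.

**Effective degrees of freedom.** Correlation significance uses a Fisher
z-test with `df = T_used / A_j`, where `A_j` is the sum of squared
autocorrelations of the equivalent level-`j` detail filter (≈1.75, 2.5,
5.0, 10.0 for la8 levels 1–4). A common shortcut divides by `2^j` instead;
Monte-Carlo null calibration in the test suite shows that shortcut is
several-fold conservative (null significant-edge counts ~4× below
`alpha * N(N-1)/2`), while the filter-based factor calibrates within a few
percent. The factor is computed once per (filter, level) from an impulse
response and cached.

**Estimator noise.** At 384 volumes, scale 3 leaves ~335 usable
coefficients and effective df ≈ 67, i.e. a per-entry correlation SE around
0.12. Pointwise convergence of the estimated matrix to the generating one
should therefore be judged by mean absolute deviation (≲0.1 at study
length, shrinking as `1/sqrt(T)`), not by the maximum over 3916 entries,
whose null expectation is ~0.45.

**Graph construction.** Distance transform `d = 1 - |r|`; edge ranking by
`|r|` descending (a signed mode exists, since "strongest correlation" is
ambiguous for negative correlations); ties broken lexicographically by
node-id pair so construction is bitwise reproducible; MST edges count
against the budget (the fixed-edge-count contract implies it). Budgets
below `N - 1` or above `N(N-1)/2` are errors, not warnings.

**Degree normalization and kappa.** Degree centrality divides by the
maximum degree in the network (a `"classic"` flag restores the `N - 1`
textbook normalization). Note a mechanical consequence: because the two
conditions are divided by *different* maxima, the kappa computed from
max-normalized degree is attenuated by `max(d_ref)/max(d_cond)` relative
to the kappa implanted on raw degrees. Parameter-recovery checks therefore
run on raw degree (`metric = "degree"`), the scale the implant inverts;
kappa on any *commonly* rescaled metric is unchanged (scale equivariance is
tested).

**Intercept.** The HDI regression fits an intercept by default — a fitted
regression line conventionally has one, and with the edge total held fixed
the implant necessarily introduces an offset `c` — while a
force-through-origin flag matches the bare proportional model. Both paths
are tested exactly on affine inputs.

**Permutation conventions.** All tests use the add-one convention
`p = (1 + #extreme) / (1 + n_perm)` so p is never zero; two-tailed p is
centered on the null mean, because the HDI nulls are not centered at zero
by construction (an uncentered option exists); Cohen's d is
`(observed - mean(null)) / sd(null)`. Default `n_perm = 10000`; tests and
examples reduce it where the answer is saturated anyway.

**Calibration study design.** Type-I calibration of the condition-swap test
uses cohorts in which both conditions are independent random realizations
of the same degree sequence — exchangeable by construction — with
*closeness* as the metric: a null implant preserves the degree sequence
exactly, so degree-based statistics are degenerate under exchange while
closeness carries realization noise. Calibration runs 400 replicates at
`n_perm = 1000`; at 200 replicates the binomial standard error (~0.015) is
wide enough for a perfectly calibrated test to drift outside a
[0.03, 0.07] acceptance band by chance.

**CCML.** Geodesic distances over a symmetrized Euclidean k-NN graph
(default `k = 6`, escalated with a warning until connected); classical MDS
initialization with `alpha` set by least-squares projection of the first
coordinate onto the covariate; BFGS minimization of raw stress
`sum (d_geo - ||y_i - y_j||)^2` jointly over `alpha` and the free
coordinates, with the first coordinate reconstructed as `alpha * kappa`
exactly (hard constraint, asserted to machine precision). A normalized
stress (`stress / sum d_geo^2`) is reported alongside. Records whose
feature columns are constant zero are refused unless overridden — a metric
with structurally absent variation (local clustering on sparse graphs)
is not a usable embedding feature. An all-equal covariate makes `alpha`
unidentifiable; the fit falls back to classical ISOMAP with a warning.

**Between-community distance.** Defined as the mean geodesic distance over
node pairs in different communities of the modularity partition (greedy
modularity maximization by default, deterministic; seeded Louvain as an
option). When the partition is trivial (one community) the quantity is
recorded as missing, never as zero.

**FDR.** Benjamini–Hochberg step-up within each result family, q = 0.05
for global families and q = 0.1 for nodal families by default.

## What the tests do and do not show

The test suite validates every stage against independent oracles:
exhaustive spanning-tree search for the MST, explicit triangle counting
and Floyd–Warshall for the metrics, exhaustive sign-flip enumeration for
the paired test, the step-up definition for FDR, and implanted-parameter
recovery for the generator (`|kappa_hat - kappa_target| <= 0.1` for
targets in {−0.8, −0.5, −0.2, 0} over 20 subjects). Problem sizes are the
study's own (89 nodes, 400 edges, 384 volumes, 28 subjects) except where a
property is size-independent, where smaller fixtures keep the suite fast.

Because the cohort is synthetic, green tests certify the arithmetic and
the statistical calibration of the pipeline on its stated model — they do
not certify robustness to preprocessing choices, motion, physiological
confounds, or atlas misregistration in real fMRI data, and the shipped
89-region node table is only partly real: 19 regions carry published MNI
centroids, the remaining 70 rows are labelled synthetic placeholders.

## Known limitations

* The disruption implant acts on degree sequences; clustering- and
  closeness-based kappas on disrupted cohorts are affected indirectly and
  have no implanted target to recover.
* The time-series propagation of disruption shrinks all correlations
  uniformly to restore positive definiteness, so condition matrices have a
  smaller dynamic range than reference matrices; graph topology (a rank
  property) is preserved, absolute correlation levels are not.
* The group-level HDI mode is provided for the node-shuffle comparison
  only; clinical cross-sectional use against external control cohorts is
  out of scope.
* Robust-regression variants of the HDI slope are not implemented; the
  index is an OLS slope by definition here.
* Mixed-effects condition contrasts are not implemented; the permutation
  comparisons are the supported inferential path.
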