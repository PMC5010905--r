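---
title: "Estimating an effective sample size for tree topologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating an effective sample size for tree topologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoess)
```

## The problem

Bayesian phylogenetic MCMC produces an autocorrelated sequence of trees.
For continuous parameters the effective sample size — the number of
independent draws carrying the same information as the correlated chain —
is routinely computed from the spectral density of the trace at frequency
zero, and samples with ESS below roughly 200 are treated as inadequate.
The topology itself has no such machinery: it is not a number, and its
autocorrelation cannot be read off a scalar trace. `topoess` closes that
gap with two estimators built on topological distances between sampled
trees, plus the two visual diagnostics they derive from.

Everything operates on *unrooted topologies with branch lengths ignored*:
branch lengths are continuous and can be monitored with conventional
tools, so rooted inputs are silently unrooted on ingest and edge lengths
dropped.

## Distances

Two metrics are supported.

* **Robinson–Foulds** (`robinson_foulds()`): the number of non-trivial
  splits (bipartitions induced by internal edges) present in exactly one
  of the two trees. Bounded by 2(n − 3) on binary trees with n leaves,
  integer-valued, coarse: quite similar trees can already be maximally
  distant.
* **Path difference** (`path_difference()`): build for each tree the
  matrix of leaf-pair path lengths counted in edges (`leaf_path_matrix()`,
  rows and columns in lexicographic label order so matrices subtract
  cleanly), then take the Euclidean norm of the matrix difference. Much
  finer-grained, and therefore the package default for ESS work: the more
  distinct values a metric can take, the better it resolves
  autocorrelation.

Internally, chains are deduplicated by topology and represented either by
their path-length vectors (path difference, giving vectorized pair
distances) or by canonical split-key sets (Robinson–Foulds); when a chain
visits few distinct topologies the full unique-by-unique distance table is
precomputed once. These are performance details only — the test suite pins
both metrics to brute-force enumerations (graph components per deleted
edge; all-pairs shortest paths) on complete sets of small trees, and to an
independent implementation.

## Diagnostics

A **topology trace** (`topology_trace()`) plots the distance from each
sampled tree to one focal tree against generation. The default focal tree
is a uniformly random member of the sample: using the first tree is
possible but produces a start-tree artefact in which early distances climb
away from the focal tree even in a perfectly stationary chain. A flat
trace is necessary but not sufficient for good mixing — distinct
topologies equidistant from the focal tree are indistinguishable on it, so
the false-negative direction exists (the false-positive one does not).

A **jump distance plot** (`jump_profile()`) shows, for each sampling
interval k from 1 to ⌊N/10⌋, the mean distance over all overlapping pairs
(i, i + k). All N − k pairs at each lag are used — no pair subsampling.
When more than 100 lags exist, a deterministic near-even subsample of
exactly 100 (endpoints forced, no RNG) keeps the profile readable and the
cost bounded. Flat profile ⇒ uncorrelated samples; rising profile ⇒
autocorrelation, with the saturation lag estimating the autocorrelation
time; a profile still rising at lag ⌊N/10⌋ only bounds that time from
below. Both diagnostics assume a stationary, adequately mixing chain —
assessed with the trace — before the profile (and the approximate-ESS
built on it) is interpreted.

## Pseudo-ESS

`pseudo_ess()` converts the sample into the univariate
distance-to-focal-tree trace and applies the standard spectral ESS
estimator (`coda::effectiveSize()`: AR model with AIC-selected order for
the spectral density at zero). Because no focal tree is privileged — and
no single choice is guaranteed to yield the smallest ESS, hence "pseudo" —
the estimate is replicated with 100 random focal trees drawn without
replacement and summarised by the median and the 2.5%/97.5% percentiles.
The replicate spread is part of the result: on difficult posteriors the
largest and smallest replicate can differ by an order of magnitude.
Pseudo-ESS values are deliberately *not* clamped to N (the estimator can
legitimately exceed it on near-independent samples); values above N are
flagged instead. A constant trace returns N with a `flat_sample` flag and
a warning, the flat-trace false negative made explicit.

## Approximate-ESS

`approximate_ess()` treats the expected squared pairwise distance as the
analogue of covariance. Let D be the expected squared distance between two
independent topologies from the posterior and f(k) the expected squared
distance at lag k, with m the smallest lag at which samples are
independent. The number of independent samples M with matching expected
squared distance solves

$$\frac{M(M-1)}{4M^2} D = \frac{\sum_{i=1}^{N-1}\sum_{k=1}^{\min(m, N-i)} f(k)
 + \frac{(N-m+1)(N-m)}{2} D}{2N^2}.$$

Dividing by D and writing r for the right-hand side, M = 1/(1 − 4r). The
right-hand side is the expected total squared distance over all N(N−1)/2
sample pairs with *each pair counted exactly once* — f(k) for pairs at lag
k < m, D for pairs at lag ≥ m — and is evaluated in closed form as
Σ_{k<m} (N−k)f(k) + (N−m+1)(N−m)/2 · D (the suite pins this against a
literal loop over every pair at 10⁻⁹). The counted-once reading matters:
with the inner summation bound min(m, N−i) taken literally, pairs at lag
exactly m enter both the double sum (as f(m) = D) and the tail term.
That double count looks innocuous but is not: writing ρ_k = 1 − f(k)/D
for the implied autocorrelation at lag k, the counted-once equation
reduces (to O(1/N)) to the classical M = N/(1 + 2Σρ_k), whereas the
double-counted version gives M ≈ N/(2Σρ_k − 1) — about twice the ESS at
moderate mixing, and a clamp to N whenever Σρ_k < 1. Only the
counted-once form reproduces the agreement between the approximate- and
pseudo-ESS that motivates the method, so it is the implementation here
(the double-counted variant remains available internally for comparison).

Estimation plugs in empirical quantities: f(k) for k < m is the mean
squared distance over all pairs at lag k (lags missing from a subsampled
profile are computed on demand), and D is the pooled (pair-count-weighted)
mean squared distance over all profiled lags ≥ m. The fitted semivariogram
is used *only* to locate m, never as a smoother of f — a fitted-f variant
was considered and rejected to keep the estimator faithful to the
empirical profile.

Substituting m = 1 (no autocorrelation) gives r = (N−1)/4N and hence
M = N exactly: an i.i.d. chain reports the full chain length with no
clamping needed. Noise can still push r to ¼ or beyond (an
apparently over-dispersed profile), so the solution is clamped to [1, N].
This also makes the estimator *granular*
near N: m is an integer, so as mixing degrades the value stays at N until
the fitted m ticks from 1 to 2, then jumps. The suite asserts this
piecewise-constancy in m directly. Granularity is harmless in practice
because the diagnostic question is whether the ESS is far below N, not
its exact value near N.

### Locating m: the semivariogram fit

`fit_semivariogram()` fits f(k) = D(1 − e^(−k/a)) to the profile of mean
squared distances by least squares. The range form e^(−k/a) is used
throughout (the product form e^(−ka) is the same model with a ↦ 1/a; the
reported `a` always refers to the range form). Fitting is deterministic:
`optim()` (L-BFGS-B, both parameters bounded positive, objective tolerance
1e−8) from the scale-aware start D₀ = max observed mean squared distance,
a₀ = smallest lag exceeding (1 − e⁻¹)D₀; because a two-parameter descent
can stall on very flat or very steep profiles, the result is refined by a
profiled line search over a (the model is linear in D given a, so D has a
closed form) and the lower-objective solution is kept. On noiseless curves
with D ∈ [10, 10⁴] and a ∈ [0.5, 50] both parameters are recovered to
better than 1%.

m is then the smallest integer lag at which the fitted curve reaches a
fraction `asymptote_threshold` of D: m = ⌈−a·ln(1 − threshold)⌉. The
threshold defaults to 0.95 (m = ⌈a ln 20⌉). No canonical value exists for
this cutoff — published jump-plot asymptote judgements are visual — so
0.95 is this package's operationalisation, exposed as an argument.

Degenerate cases: an all-zero profile (identical trees) short-circuits to
a `flat` status and both estimators report N with a `flat_sample` flag —
a possible false negative, flagged rather than failed. If m exceeds the
largest profiled lag the asymptote was not reached: D is replaced by the
largest observed mean squared distance (a lower bound on the true sill)
and m set to one past the largest profiled lag (the smallest value
consistent with non-saturation). Underestimating both inflates M, so the
result is reported with `is_upper_bound = TRUE` — an upper bound is still
diagnostic, since the chain is by then clearly inadequate.

## The simulators

No method exists to simulate a phylogenetic MCMC with *known* topology
ESS, so validation uses chains in which the ESS varies predictably.

`simulate_unimodal()` starts from a random topology (sequential random
leaf attachment, leaves `t1..tn`) and applies a fixed number of random SPR
moves between successive samples — an MCMC walk with no data, where more
moves per step mean less autocorrelation. Defaults (50 taxa, 1,000
samples) match the reference design; with 1 move per step the chain is
strongly autocorrelated, while around 200 moves at 50 taxa successive
samples are essentially independent.

`simulate_bimodal()` emulates a bimodal posterior (e.g. two concatenated
loci with conflicting histories): two sets of 10 trees whose seed
topologies are 50 SPR moves apart, satellites 1 move from each seed; the
chain switches sets with probability `switch_prob` and samples uniformly
(with replacement) within the current set. `switch_prob` is the
probability of *switching*: at 0 the chain never reveals the second mode
and its sample is indistinguishable from perfect mixing over set 1 (both
estimators should — and do — report N), while at 0.5 membership is an
i.i.d. coin flip. Both simulators are fully reproducible from a single
seed, down to byte-identical newick output.

What these chains do *not* emulate: posterior weights from data (every
topology reached is implicitly equally likely), branch lengths, and the
within-mode correlation structure of real BEAST/MrBayes samplers. Passing
tests on them shows the estimators track autocorrelation and
multimodality as designed, not that any particular empirical chain is
adequate.

## Numerical and design choices

* Metrics count path lengths in edges, never branch-length sums; RF uses
  non-trivial splits only (required for the 2(n − 3) bound).
* Leaf order for path matrices is lexicographic by label (radix order,
  locale-independent), fixed once per sample.
* Pseudo-ESS focal trees are drawn *without* replacement (duplicate focal
  trees add no information); `n_replicates > N` is an error.
* All randomness flows from explicit `seed` arguments through R's RNG;
  replicate focal indices are returned for auditability.
* `sampling_intervals()` subsampling is `round(seq(...))` with endpoints
  forced and duplicates repaired — deterministic, no RNG.
* SPR/NNI *distances* (as opposed to SPR moves) are not implemented; they
  are expensive and add nothing to the ESS machinery here.

## Problem sizes

The test suite and the reproduction script run entirely on simulated
chains at the reference scale of 1,000 trees: mixing sweeps use 5 seeds
per design point (SPR moves ∈ {1, 2, 5, 10, 20, 50} at 50 taxa; switch
probability ∈ {0.01, 0.1, 0.2, 0.3, 0.4, 0.5}), oracle-equivalence checks
enumerate all topologies on up to 7 leaves, and the closed-form/brute-force
agreement check for r runs at N ≤ 200 where the double loop is cheap.

## Known limitations

* Both estimators are only as good as the distance metric's ability to
  discriminate topologies; RF-based estimates are systematically coarser
  (and tend lower) than path-difference ones on the same chains.
* The approximate-ESS assumes the jump profile comes from a well-mixed,
  stationary chain; on a chain stuck in one mode of a multimodal posterior
  it will happily report a large ESS (so will every other single-chain
  diagnostic — compare replicate chains with `cmd_compare()`).
* The pseudo-ESS depends on the focal tree; report the replicate interval,
  not just the median.
* Non-integer autocorrelation times are not representable: the
  approximate-ESS moves in discrete jumps near N.
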