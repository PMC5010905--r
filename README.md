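# topoess

Convergence diagnostics and effective sample size (ESS) estimation for
**tree topologies** sampled by Bayesian phylogenetic MCMC.

Tools such as Tracer report the ESS of every continuous parameter of a
Bayesian phylogenetic analysis, but the parameter users usually care most
about — the tree topology — is not continuous, and the standard
autocorrelation machinery does not apply to it. A chain can look healthy on
all of its scalar traces while its sampled topologies are still strongly
autocorrelated. `topoess` is for anyone running BEAST/MrBayes-style
analyses (or developing samplers) who wants the topology held to the same
"ESS ≥ 200" standard as everything else.

## What it computes

All methods work on topological distances between sampled trees, ignoring
branch lengths. Two metrics are provided: the Robinson–Foulds distance
(splits present in exactly one tree) and the **path difference**
(Euclidean norm of the difference of leaf-pair path-length matrices), the
default because it discriminates tree pairs much more finely.

- **Topology traces** — the distance of every sampled tree to a focal
  tree, plotted against generation: the tree analogue of a parameter
  trace.
- **Jump distance plots** — the mean distance between pairs of trees at
  increasing sampling intervals (lags 1 … ⌊N/10⌋, capped at 100 lags): flat
  means uncorrelated samples, a rising curve that saturates estimates the
  autocorrelation time.
- **Pseudo-ESS** — apply the standard spectral ESS estimator to the
  distance-to-focal-tree trace; since the focal tree is arbitrary, this is
  replicated over 100 random focal trees and summarised by the median and
  95% percentile interval.
- **Approximate-ESS** — equate the expected squared pairwise distance of
  the chain with that of M independent draws and solve for M. With D the
  expected squared distance between independent topologies, f(k) the
  expected squared distance at lag k, and m the autocorrelation time
  (located by fitting the exponential semivariogram
  f(k) = D(1 − e^(−k/a)) to the jump profile):

  M(M−1)/(4M²) · D = [ Σₖ₌₁^{m−1} (N−k) f(k)
                       + (N−m+1)(N−m)/2 · D ] / (2N²)

  (every sample pair counted once: f(k) at lag k < m, D at lag ≥ m),
  solved as M = 1/(1 − 4r) and clamped to [1, N]; in terms of the implied
  autocorrelations ρₖ = 1 − f(k)/D this is the classical
  M = N/(1 + 2Σρₖ). If the profile never saturates, D is replaced by the
  largest observed mean squared distance and the result is reported as an
  upper bound.

Two chain simulators used to validate the estimators ship as first-class
functions: unimodal SPR-walk chains (a fixed number of random
subtree-prune-regraft moves between successive samples) and bimodal
two-set switching chains (two distant sets of 10 trees, switched between
with probability `switch_prob`).

## Worked example

```r
library(topoess)

# a poorly mixing chain: 1,000 trees of 50 taxa, 1 SPR move per step
ts <- simulate_unimodal(n_taxa = 50, n_samples = 1000, sprs_per_step = 1,
                        seed = 7)

cmp <- compare_ess(ts, seed = 2)
tidy(cmp)
#> # A tibble: 2 × 8
#>   method      metric          value ci_low ci_high is_upper_bound     N flags
#>   <chr>       <chr>           <dbl>  <dbl>   <dbl> <lgl>          <int> <chr>
#> 1 pseudo      path_difference  35.5   23.1    52.3 FALSE           1000 ""
#> 2 approximate path_difference  48.4   NA      NA   FALSE           1000 ""
```

Both estimators agree that these 1,000 correlated samples are worth only
about 35–50 independent topologies — far below the usual 200 cutoff, so
this analysis would need to run much longer (or mix better). The 95%
interval on the pseudo-ESS reflects its dependence on the arbitrary focal
tree. For a well-mixed chain both estimators rise to the chain length:

```r
ts2 <- simulate_bimodal(n_taxa = 50, n_samples = 1000, switch_prob = 0,
                        seed = 42)
glance(compare_ess(ts2, seed = 1))
#> # A tibble: 1 × 4
#>   pseudo approximate approx_within_ci     N
#>    <dbl>       <dbl> <lgl>            <int>
#> 1  1000.        1000 TRUE              1000
```

Visual diagnostics:

```r
autoplot(topology_trace(ts, seed = 1))   # trace vs generation
autoplot(jump_profile(ts))               # mean distance vs sampling interval
```

A thin command-line wrapper is installed at `exec/topoess`
(`topoess analyze --trees chain.nwk --out run1 --seed 1`); it writes
`trace.tsv`, `jump.tsv`, `ess.tsv` and a `manifest.json` that reproduces
the run.

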