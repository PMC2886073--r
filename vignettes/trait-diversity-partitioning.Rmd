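---
title: "Partitioning trait diversity along a phylogeny: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait diversity along a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raopart)
```

## The model

`raopart` asks how the diversity of a quantitative trait distributes over
a rooted phylogeny, and specifically how much of it lies *within* species.
The data are a branch-length-free classification (a topology with labelled
tips, polytomies allowed) and a trait table with one measurement per
species × population. The method has three ingredients.

**Virtual sister-taxa.** A species with two or more population-level
measurements has its tip replaced, in place, by an *artificial node* whose
children are one virtual tip per population. Because the tree carries no
branch lengths, no assumption about the age of these new nodes is needed.
Species with a single measurement stay ordinary tips. The resulting
*enlarged tree* holds intra- and inter-specific variation in one
structure.

**Quadratic-entropy decomposition.** Trait diversity is Rao's quadratic
entropy: the mean pairwise dissimilarity among tips, `sum_ij d_ij / n^2`.
With the single-trait dissimilarity `d_ij = (x_i - x_j)^2 / 2` this equals
the variance with divisor `n`. The general pairwise form is implemented
(`quadratic_entropy()` accepts a dissimilarity matrix) so a multi-trait
extension remains possible, but only the single-trait path is exercised
here. Each internal node `k` receives

$$d_k = \mathrm{QE}(\text{tips under } k)
  - \sum_j \frac{n_j}{n_k}\,\mathrm{QE}(\text{tips under child } j),
  \qquad \nu_k = p_k d_k,\; p_k = n_k/n,$$

which, by the law of total variance, makes `d_k` the size-weighted
variance of the child-clade means. The contributions telescope:
`sum(nu_k)` equals the total quadratic entropy exactly (the suite checks
this to 1e-10 on random polytomous trees). `p_k` counts tips of the
*enlarged* tree, so species with more populations weigh more — a
deliberate property: evidence about within-species variability should
scale with the amount of replication.

**Permutation inference.** Three statistics summarise the decomposition,
each tested by permuting trait values jointly across *all* tips of the
enlarged tree. That null model declares intra- and inter-specific
variation exchangeable: the diversity among species below an
inter-specific node is equivalent to the diversity among populations below
an artificial node. Permutations alter the `d_k` while the `p_k` stay
fixed.

* `S_c` (sum of `nu_k` over artificial nodes; the intra-specific share of
  trait variance once values are standardized) — alternative `less`;
  trait conservation within species shows up as an unusually small
  intra-specific share. `S_c` equals the within-species share of the
  total sum of squares computed with no tree at all, which the test suite
  uses as an exact oracle.
* `S_3` (contribution-weighted mean of tipward depth ranks) — two-sided,
  with the doubled-smaller-tail rule capped at 1. Small values mean
  diversity held by root-ward nodes.
* Abouheif's `C_mean` (Moran-form autocorrelation with path-product
  proximities, zero diagonal, no row normalization) on species means,
  upper-tailed — a phylogenetic-signal screen on the inter-specific
  component alone.

P-values use the `(r + 1)/(N + 1)` estimator, which keeps the tests valid
(p is never 0) at the cost of effectively counting the observed value into
the null set. Each test requires an explicit integer seed, recorded in the
result object. Across several metrics, p-values are Hochberg-adjusted
within each statistic family (one family per statistic, families never
pooled): the step-up procedure controls the family-wise error rate while
being uniformly less conservative than Bonferroni.

## Depth ranks

`S_3` needs the internal nodes ordered by their distance to the tips.
Depth is the *maximum* edge-count distance from a node to any of its
descendant tips, measured on a *reference* classification (typically the
full tree the analysis tree was pruned from) at the reference node
spanning the same species. Using the reference avoids artefacts of
unbalanced pruning: a clade that looks shallow after pruning keeps the
depth it has in the full classification. Max (not min) distance is used
because it is stable when one child lineage is pruned away. Nodes are
ranked by decreasing depth, ties receive average ranks, and ranks are
mapped affinely onto [0, 1] with 0 for the deepest node. Two conventions
had to be fixed where no published rule exists:

* **Artificial nodes get rank 1.** They hang below original species tips,
  hence are closer to the tips than any node of the reference
  classification. This is this package's convention.
* **Degenerate case.** If all non-artificial internal nodes share one
  depth (a star tree), the affine map is undefined; all are assigned rank
  0 (the "deepest" convention).

## Trait preprocessing

Within each metric, the pooled species × population values are Box-Cox
transformed and then standardized to zero mean and unit *population*
variance (divisor `n`). Divisor `n` rather than `n - 1` is used everywhere
so that the decomposition is exactly additive and node contributions read
directly as proportions of a total of 1; centering does not affect any
statistic (they depend only on value differences) but is numerically
hygienic. The Box-Cox exponent maximizes the univariate profile
log-likelihood over λ ∈ [−5, 5] (`stats::optimize`, tolerance 1e-8), with
the log branch taken for |λ| < 1e-10. Non-positive values are first
shifted by `-min + 1e-6 · range`. The fit is on pooled values (not species
means) because the tips of the enlarged tree are populations; both the
shift rule and the pooled fit are this package's choices where the
procedure was underspecified. With λ fixed at 1 the transform is affine
and the standardized values are unchanged — a property the tests assert.

## The synthetic-data generator

Because the motivating dispersal dataset is not deposited, the package
ships a generator that emulates its shape and makes every statistic
testable:

* `simulate_yule_topology()` — pure-birth topology (via random joins,
  which draws from the same distribution over labelled topologies as
  uniform lineage splitting), tips `sp001...`, no branch lengths.
* `simulate_bm_trait()` — Brownian walk with unit-length edges and
  innovation sd `sigma_between`, root value 0. This supplies phylogenetic
  signal for exercising `C_mean` and `S_3`; it is a fixture model only,
  never used for inference.
* `add_population_replicates()` — iid Normal(μ_s, σ_w²) draws per
  population; a single-population species copies its value exactly.
* `simulate_scenario()` — ties these together with a *calibrated*
  within-species variance share. For tips `x_sp = μ_s + e_sp` the
  expectations are `E[SSw/n] = σ_w²(n−m)/n` and
  `E[SSb/n] = Var_n(μ) + σ_w²(m−1)/n` (`n` tips, `m` species): the
  between-species sum of squares is inflated by sampling noise in the
  population means. The generator solves these for σ_w given the realized
  `Var_n(μ)` so that the expected within-share equals the requested `w`
  exactly; ignoring the inflation term would bias the realized share low
  by up to ~0.07 at `w = 0.5`. A share is attainable only for
  `w < (n−m)/(n−1)`; the generator refuses impossible designs. The
  default design (18 species, 8 replicated with 3–6 populations in
  `write_fixture_dataset()`) mirrors the shape of published butterfly
  dispersal compilations (10–28 species per metric, 3–11 replicated,
  up to 8 populations).

What the generator does *not* emulate: measurement error within
populations, non-normal trait distributions before transformation,
metric-specific missingness patterns, and any correlation between
replication effort and trait values. Passing tests therefore show the
machinery is correct under a clean nested-variance model, not that real
dispersal data meet these assumptions.

One subtlety the suite documents: under the permutation null the expected
`S_c` is `(n − m)/(n − 1)`, *not* 0.5. Conservation-test p-values are
therefore approximately uniform only when the designed within-share
matches that value — the uniformity check uses 12 species × 2 populations
with `w = 12/23 ≈ 0.52`. With, say, four populations per species the null
expectation is ≈ 0.75 and a generator share of 0.5 is (correctly) rejected
nearly always. The residual Kolmogorov distance bound (0.08) reflects that
the Brownian between-species structure never matches tip exchangeability
exactly.

## Numerical choices

* Floating-point cancellation can push a node's `d_k` slightly negative;
  values above `−1e-12` (relative to the clade's QE) are clamped to 0,
  anything larger raises an internal-consistency error.
* Permutation tail counts use a relative tolerance of 1e-12 at the
  observed value, counting exact ties into the tail (conservative).
* Permutation loops re-evaluate node contributions through a precomputed
  index plan (tip sets per node and per child); this is the same formula
  as the full decomposition, specialized for speed, and the suite checks
  the two paths agree.
* Seeds: every stochastic function takes a mandatory seed and runs under a
  saved-and-restored RNG state. Simulation studies inside the test suite
  draw per-test seeds from one outer seeded stream rather than using
  sequential constants, which avoids cross-correlated Mersenne-Twister
  streams that overdisperse Monte-Carlo summaries.
* Problem sizes in the routine suite were chosen to characterize the
  estimators well at interactive speeds: identity and oracle checks on 200
  random trees/scenarios, type-I error on 1200 datasets × 199 permutations
  per test, recovery on 200 datasets per target share, exhaustive-vs-Monte
  Carlo agreement on 4–6-tip trees at 2000 permutations.

## Known limitations

* The `S_3` statistic is a reconstruction from the described behaviour
  (ordering rule, sign convention, [0, 1] range); published values
  computed with other software are not expected to match digit-for-digit,
  and the bundled butterfly reference table is used for arithmetic on the
  published S_c column, never as a regression target.
* Only a single quantitative trait is supported end to end; the
  quadratic-entropy core accepts general dissimilarities but the pipeline
  does not.
* The conservation test compares artificial nodes against *all* other
  nodes jointly; per-node or per-clade versions (testing one species or
  one region of the tree) are not implemented.
* Branch-length-aware diversity partitioning is out of scope by design:
  the input trees are classifications without lengths.
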