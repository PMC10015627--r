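---
title: "Models and methods in phyloregime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phyloregime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloregime)
```

`phyloregime` studies how a binary reproductive-mode regime — selfing
versus outcrossing — shapes continuous genome traits and gene-family
content on a rooted phylogeny. This vignette is the package's own account
of the models it fits, the defaults it chooses where several defensible
options exist, and what its synthetic-data tests do and do not establish
about real data.

## Trees and regime paintings

Trees are standard `ape::phylo` objects; branch lengths may be
substitutions/site or any proportional time scale, and trees need not be
ultrametric except for gene-family turnover (whose transition model
assumes a common time depth). Three small surgeries support typical study
designs:

* `graft_tips_as_polytomy()` attaches conspecific strains to a species tip
  with branch length 0 by default. Strain divergences are negligible on a
  genus-level tree and inventing lengths would distort every covariance
  matrix; with zero lengths all pre-existing patristic distances, and all
  likelihoods in which the strains carry no data, are provably unchanged.
* `resolve_polytomies()` resolves multifurcations left-to-right in input
  order with zero-length inserted branches (`ape::multi2di(random =
  FALSE)`), so resolution is deterministic and likelihood-inert.
* `make_ultrametric(method = "extend")` lengthens terminal branches to the
  maximum root-to-tip depth. Extension is order-independent, never
  shortens a branch, and touches only terminal branches; smoothing methods
  (e.g. rate-penalized) would re-estimate every length and are out of
  scope.

A *regime painting* stores one state per branch, keyed by the branch's
child node: a branch's regime is what the lineage is by the time it ends.
The alternative (parent-node state) would date each regime's origin one
node earlier; the choice matters only for the branches on which
transitions happen, and is configurable where it is consumed.

## Regime inference (Mk models)

Tip states are modelled by a two-state continuous-time Markov chain with
the closed-form transition matrix; `ER` and `SYM` constrain the rates to
be equal (for a binary character these are the *same* model, and the
package asserts their fits agree to 1e-9 rather than deduplicating them,
since the three-model ladder is how results are conventionally reported),
and `ARD` frees both rates. Fitting maximizes the pruning likelihood on
the log-rate scale within `[1e-8, 1e3]` per unit branch length from three
deterministic starts (0.1, 1, 10 expected transitions per tree height);
the surface is one- or two-dimensional and smooth, so this is cheap
insurance against flat-likelihood failures. AICc uses `n` = number of
tips — tips are the exchangeable sampling units; using site- or
branch-counts would be incoherent for a single character.

The root prior is flat (0.5, 0.5) by default, the common maximum-likelihood
ancestral-state convention; a stationary prior is available. Marginal
ancestral probabilities come from a combined upward/downward
(re-rooting) pass validated against exhaustive enumeration on small trees.
`paint_regimes()` discretizes by child-node argmax; exact ties inherit the
parent's already-resolved state (a root tie falls to outcrosser) and are
flagged rather than silently resolved.

## Ancestral genome size (Brownian motion, REML)

The BM rate is estimated by restricted maximum likelihood — equivalently
the mean square of the standardized phylogenetically independent
contrasts — which removes the downward bias ML incurs from estimating the
ancestral mean. Node states are GLS/BLUP conditional expectations under
the fitted rate, with conditional variances that include the root-mean
estimation variance (so the root's 95% CI is `mu_hat +/- 1.96
sigma/sqrt(1'V^-1 1)`, not a point). Intervals use the normal 1.96
multiplier and condition on the REML rate; with few tips the rate is
itself uncertain, so realized coverage runs a little below nominal (the
test suite measures about 93–94% at 11–50 tips and checks it stays within
95 +/- 3). Zero-length sister tips (grafted strains with identical data
slots) make the tip covariance singular; terminal variances are floored
by 1e-12 and flagged instead of failing.

## Adaptation models (BM / OU1 / OU2)

The Ornstein-Uhlenbeck model `dy = -alpha (y - theta) dt + sigma dW` is
parameterized by the regime optima `theta` (trait units), the adaptation
rate `alpha` (per unit branch length), and is reported through the more
interpretable phylogenetic half-life `t1/2 = ln 2 / alpha` (branch-length
units, also as a fraction of tree height) and stationary variance
`v = sigma^2 / 2 alpha` (trait units squared). Tip expectations follow the
Hansen weighting of each root-to-tip path's regime segments; covariances
use depth-based formulas that do not assume ultrametry. Traits are
analyzed on their natural scale (Mb, percent of genome) because optima are
interpreted on that scale; no log transform is applied.

Numerical strategy: `alpha` is profiled by a deterministic 50-point log
grid over half-lives spanning `[1e-4, 10] x` tree height with local
golden-section refinement (OU surfaces are flat in `alpha`; a reproducible
grid beats quasi-Newton restarts here), while the optima and `v` have
closed-form GLS/profile solutions at each grid point. Fits whose optimum
sits on the grid boundary are flagged. The root trait value is tied to the
root regime's optimum by default, giving k = 2 (BM: mean, rate), 3 (OU1),
4 (OU2) parameters; `estimate_root = TRUE` frees it. With strong
adaptation the root value is nearly unidentifiable, and tying it keeps the
model count honest.

Optima standard errors come from the observed information matrix of
(`theta`, `log alpha`, `log v`) by central finite differences, falling
back to the conditional GLS covariance when the information matrix is not
positive definite. The conditional GLS SE understates uncertainty
precisely where it matters most — a regime occupying only short terminal
branches extrapolates its optimum through `alpha` — and the recovery
experiments in the test suite (optima within 2 SE in at least 90 of 100
simulated datasets at the fixture effect size) hold with the
information-based SEs but not with the conditional ones.

`r^2` is defined in the GLS metric: `1 - RSS/TSS` with V-weighted
residuals about the V-weighted mean. `compare_models()` ranks by AICc
(n = number of tip genomes), marks everything within 2 units of the best
as indistinguishable, and breaks exact ties toward fewer parameters.

## Gene-family turnover (birth-death)

Family counts evolve by the critical linear birth-death process: each gene
duplicates and dies at the same rate `lambda` (per gene per unit branch
length), so the transition probability depends only on
`a = lambda t / (1 + lambda t)`, and zero copies is absorbing. Equal birth
and death keeps the process mean-preserving and the model one-parameter
per branch class; independent birth and death rates are out of scope.
Transition matrices are built by repeated convolution of the single-gene
row (descendants of the starting genes are independent), which agrees
with the closed-form sum to rounding error and is far faster. Pruning runs
over count states `0..N_max` with `N_max = max(2 x max count, 30)`;
row-sum (truncation-tail) error is checked in the tests at 1e-9. The root
prior is uniform on `{1..N_max}` — a family must have at least one
ancestral representative — and is configurable. The optional count-error
model is a symmetric +/-1 misobservation with probability `eps`
(profiled over a `{0, 0.01, ..., 0.2}` grid when requested), a documented
simplification of full error matrices; its boundary rows fold impossible
observations back into staying, so emissions remain proper distributions.

With two rate classes the default branch partition is selfer versus
outcrosser branches taken from the painting — the hypothesis-driven
partition in a reproductive-mode study — and any explicit partition can be
supplied. Models with different numbers of rates are compared by AICc with
`n` = number of families.

### Family significance

Per-family log-likelihoods are not comparable across family sizes, so
significance conditions on ancestral size. The distribution of root counts
is first estimated from the data by EM on the mixing distribution
(empirical Bayes, 3 iterations — enough for a 1000-family matrix to
stabilize); each family then draws one root count from its posterior
under that prior. By Bayes' rule the sampled (root, data) pair is a draw
from the joint null, so the Monte-Carlo rank of the family's
log-likelihood among `M` null families forward-simulated from the same
root count is uniform under the fitted null. Count patterns repeat
heavily, so likelihood ties are randomized uniformly across each tie
block — the standard construction for discrete Monte-Carlo tests; without
it the all-equal-counts atom alone visibly distorts the null p-value
distribution. The attainable minimum p is `1/(M+1)`; `M = 1000` by
default, seeded. Storey q-values (pi0 from the flat right tail over a
lambda grid, spline-smoothed, BH fallback whenever the estimate is
unstable) correct for multiple testing; downstream analyses use q < 0.01.

### Ancestral counts and parallel-change classification

`reconstruct_changes()` finds the jointly most probable ancestral count
assignment by max-product dynamic programming, breaking ties toward the
smallest count (flagged). A tip's *lineage* is the path from where its
current regime originated (walking rootward while the painted state is
unchanged) down to the tip, and its net change is tip count minus the
count at the path start. The four parallel categories require every
lineage of the focal regime to be stable-or-changing in the focal
direction with at least one strict change, and every lineage of the other
regime to be stable-or-changing the opposite way; all-zero nets are
`Stable`, mixed signs within a regime class `Unclassified`. Because
"selfers strictly down, outcrossers strictly up" satisfies two category
definitions at once, rules are evaluated in a fixed order (decreasing in
selfers, increasing in selfers, decreasing in outcrossers, increasing in
outcrossers), naming the pattern by the regime that shows the strict
change first. Fisher's exact test supplies enrichment p-values; the odds
ratio is reported as the sample cross-product rather than the conditional
MLE because it is the quantity readers compute from the printed table.

## The synthetic-data generator

Simulators are exact (OU per-branch transition densities, per-gene
Gillespie birth-death, exponential-waiting-time regime histories) — no
Euler discretization anywhere, so estimator tests are free of
discretization bias. The 11-taxon fixture mirrors an Elegans-group-like
design: a binary ultrametric tree of height 1 with four selfing tips in
three independent origins, two of them conspecific strains splitting at
depth 0.98. Its trait layers use a genome-size-like BM trait (root 150 Mb,
rate 4000 Mb^2 per unit height — chosen to span the one-to-few-hundred Mb
range typical of nematode genomes) and a Mutator-like percent trait under
OU2 with optima 2.97 and 6.19, half-life 5% of tree height and stationary
variance 1.35; gene families use `lambda = 0.43` with a shifted-geometric
root prior of mean 5, a typical orthogroup-size scale. Percent traits are
simulated untruncated because the inference model is Gaussian; truncation
is available as a display-only view so estimator tests stay unbiased.

What passing tests show — and what they do not: the generator reproduces
the *statistical structure the models assume* (Gaussian OU traits,
independent families, a clean binary regime history). Real repeat-content
data add annotation noise, compositional constraints (percentages bounded
and summing below 100), orthogroup-inference errors and contamination,
none of which are simulated; results on real matrices therefore inherit
whatever upstream filtering produced them.

## Problem sizes and determinism

Every stochastic function takes a mandatory seed and restores the caller's
RNG state. The test suite uses: exhaustive-enumeration oracles on trees of
3–6 tips; 100-seed recovery experiments for the OU2 optima and the
birth-death rate (500 families); 100-replicate calibration of the
two-AICc-unit rule; 1000 families for p-value uniformity; about 2200
node-replicates for CI coverage; and 20-replicate power checks for the
asymmetric-rates and two-rate-class detections with thresholds set to the
same per-replicate power as their 100-replicate analogues. The pipeline
writes numbers with fixed 10-significant-digit formatting so identical
(config, seed) runs are byte-identical.

## Known limitations

* Two regimes only; no more than two OU optima and no trait-on-trait OU
  regressions.
* No measurement-error variance in continuous traits.
* No stochastic character mapping; regime paintings are argmax
  discretizations, and downstream models condition on a single painting.
* Gene-family birth and death rates are tied; the error model is +/-1
  symmetric.
* Ancestral CIs condition on the REML rate (slightly anti-conservative at
  small n, quantified above).
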