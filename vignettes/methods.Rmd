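---
title: "Models and methods: multifunctionality, assembly null models and co-occurrence networks"
author: "floodmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodmicro)
```

`floodmicro` implements the downstream community-ecology computations of a
multi-kingdom soil microbiome survey under a replicated factorial field
design (replicates x treatments x vegetation communities x seasons). This
vignette explains each model, the tunable parameters and their defaults,
the numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## Ecosystem multifunctionality

Every function variable $X$ (enzyme activities, total C and N, available
nutrients, pH, respiration rates; 20 columns by default) is rescaled to a
common 0–1 scale with the min–max transform

$$STD = \frac{X - X_{\min}}{X_{\max} - X_{\min}},$$

where the minimum and maximum are taken **across all samples pooled** —
never per group — so that seasonal or treatment contrasts remain visible
after standardization. The per-sample multifunctionality index is the
arithmetic mean of the standardized columns (the averaging approach; no
thresholds, no weights).

Two edge cases need a rule the transform itself does not give:

* a **constant column** ($X_{\max} = X_{\min}$) is mapped to all zeros with
  a warning, which keeps the number of functions fixed without dividing by
  zero;
* all variables are treated as "larger is more function", **including pH**.
  pH is not monotonically "good", but the averaging index has no
  direction-correction convention that is obviously right, so the package
  applies none and documents the choice here. Users who prefer a reflected
  pH can transform the column before calling `min_max_standardize()`.

Group comparisons use one-way fixed-effects ANOVA plus pairwise Welch
t-tests (unequal variances are the norm for field measurements). A pair of
zero-variance groups would break `t.test()`; the package instead reports
t = 0, p = 1 when the constants coincide and p = 0 with a `degenerate`
flag when they differ.

## Diversity and permutation tests

Alpha diversity is observed richness, Shannon entropy with the **natural
logarithm** (so a uniform community of $S$ taxa attains $\ln S$), and
Faith's phylogenetic diversity in the **rooted convention**: the branch sum
of the minimal subtree spanning the present tips *and the root*, so a
single-taxon community has the positive PD of its root path. Conventions
differ between software packages on exactly this point, which is why it is
stated prominently here. No rarefaction or relative-abundance conversion is
applied before diversity computation.

Beta diversity is Bray–Curtis, $\sum_i |a_i-b_i| / \sum_i (a_i+b_i)$.
One-factor PERMANOVA partitions the squared distances into among- and
within-group sums of squares and reports the pseudo-F; the Mantel test
correlates the upper triangles of two distance matrices. Both use
permutation p-values with the +1 correction,

$$p = \frac{1 + \#\{T_{perm} \ge T_{obs}\}}{1 + n_{perm}},$$

defaulting to 999 permutations, so p is never exactly zero and its floor is
$1/(n_{perm}+1)$. Both also offer `exact = TRUE`, which enumerates all
distinct group assignments (PERMANOVA) or all label permutations (Mantel)
for small n; the test suite uses these exact modes as oracles for the
Monte-Carlo paths. Only the one-factor PERMANOVA is implemented: the
analyses this package reproduces report single-factor effects (treatment,
season), and multi-factor partitions raise design questions (strata,
interaction terms) that are out of scope.

## Community assembly: beta-MNTD, beta-NTI, RCbray, five processes

Between-community mean nearest taxon distance is abundance-weighted by
default:

$$\beta MNTD(A,B) = \tfrac12 \sum_{i \in A} f_i \min_{j \in B} d_{ij}
                  + \tfrac12 \sum_{j \in B} f_j \min_{i \in A} d_{ij},$$

with $f$ the relative abundances among present taxa and $d$ the patristic
distance; a taxon shared by both communities contributes distance zero. An
unweighted (presence–absence) mode is available behind a flag.

The null model shuffles taxa across the tips of the phylogeny: taxa keep
their per-sample abundances, only their tip positions are permuted, which
preserves richness and abundance structure while destroying phylogenetic
signal. $\beta NTI = (\beta MNTD_{obs} - \mu_{null})/\sigma_{null}$ with
999 permutations by default. One tip permutation is drawn per null
iteration and applied to **all** sample pairs; the marginal null
distribution per pair is identical to drawing nulls pair by pair, and the
shared permutation lets a compiled kernel recompute the whole beta-MNTD
matrix at once, which is what makes hundreds of nulls on dozens of samples
affordable. Results are deterministic given the seed. Pairs whose null is
degenerate (zero standard deviation, e.g. on an equidistant star tree,
or when two samples share every taxon) are returned as `NA` with a
diagnostics flag rather than as an arbitrary number. The exact mode
enumerates all tip permutations (trees up to 7 tips) and then uses the
population standard deviation of the exhaustive null.

RCbray assembles null communities that preserve each sample's observed
richness and total abundance: taxa are drawn from the regional pool with
probability proportional to occurrence frequency, each drawn taxon gets one
individual, and the remaining individuals are allocated multinomially with
probability proportional to mean relative abundance. With $n_{null}$ null
Bray–Curtis values per pair,

$$RC = 2\left[\frac{\#\{BC_{null} < BC_{obs}\} +
  \tfrac12\,\#\{BC_{null} = BC_{obs}\}}{n_{null}}\right] - 1 \in [-1, 1].$$

Ties are detected with a $10^{-12}$ tolerance.

Pairwise turnover is classified with the conventional cutoffs
$|\beta NTI| = 2$ and $|RC| = 0.95$ (configurable): $\beta NTI > 2$
variable selection, $\beta NTI < -2$ homogeneous selection, otherwise
$RC > 0.95$ dispersal limitation, $RC < -0.95$ homogenizing dispersal, and
the residual class drift/undominated. The determinism share is the two
selection classes' fraction (equivalently the share of pairs beyond the
beta-NTI threshold); stochasticity is the complement. These thresholds come
from the established assembly-null-model framework rather than from a
derivation specific to this package, and are labelled as such.

MPD (mean pairwise distance) is computed alongside MNTD because the
analyses this package follows name it, but no classification is built on
it; it is exposed as a plain statistic.

## SparCC networks, node roles, robustness

Taxon–taxon correlation on compositional count data uses the SparCC
procedure, authored in-package: per iteration, fractions are drawn from a
Dirichlet posterior (counts + 1); the log-ratio variance matrix
$T_{ij} = \mathrm{var}\,\log(f_i/f_j)$ is formed; basis variances $t_i$
are solved from the linear system implied by the sparsity assumption
(pairwise covariances average out); and

$$r_{ij} = \frac{t_i + t_j - T_{ij}}{2\sqrt{t_i t_j}}.$$

The most strongly correlated pair above the exclusion threshold is
iteratively removed from the system and the basis variances re-solved; the
reported matrix is the average over resampling iterations, clipped to
$[-1,1]$. Defaults — 20 Dirichlet iterations, exclusion threshold 0.8, up
to 10 exclusion rounds, and at least 4 taxa (below that the basis system is
underdetermined) — follow the procedure's reference settings and are all
configurable. Exclusion stops early if it would leave any taxon with fewer
than three pairs in the system. Pseudo p-values permute every taxon's
counts across samples independently (marginals preserved, associations
destroyed) and use the two-sided +1-corrected tail over 100 bootstraps by
default; the attainable floor is $1/(n_{boot}+1) \approx 0.0099$, which
matters because the default edge gate is strict (`p < 0.01`): fewer than
100 bootstraps make the gate unpassable.

Edges require $|r| > 0.6$ **and** $p < 0.01$, both strict, both
configurable. Cross-kingdom networks concatenate per-kingdom core tables
(prevalence strictly above 60% of samples, mean relative abundance strictly
above 0.1%) after per-sample relative-abundance conversion, because
kingdoms are sequenced separately at non-comparable depths; the combined
composition is rescaled to a common pseudo-depth for SparCC's
count-based resampling.

Modules come from greedy modularity maximization on absolute edge weights
(sign ignored for partitioning). Node roles use the within-module degree
z-score $Z_i$ and participation coefficient
$C_i = 1 - \sum_m (k_{im}/k_i)^2$, with the familiar quadrant cutoffs
$Z = 2.5$ and $C = 0.62$: network hubs, module hubs, connectors,
peripherals. A singleton module or one with zero degree spread would make
$Z$ undefined; the package reports $Z = 0$ with a flag.

Natural connectivity is
$\bar\lambda = \ln\bigl(\tfrac1N \sum_i e^{\lambda_i}\bigr)$ over the
eigenvalues of the **unweighted** adjacency matrix (the robustness
literature's convention; edge weights carry estimation noise that a
redundancy measure should not inherit), computed with a log-sum-exp guard.
Robustness curves remove a fraction of nodes uniformly at random without
replacement — "random and equal" removal — recompute natural connectivity,
and average over replicates; fraction 0 is the intact value exactly.
Targeted (degree-ordered) attacks are deliberately not implemented.

## The synthetic-data generator

The generators exist so that every downstream stage can be exercised, with
known ground truth, at desk scale:

* **Design**: fully crossed factorial, default 4 replicates x 4 treatments
  (control, glyphosate, nitrogen, both) x 3 vegetation communities x 2
  seasons = 96 samples, every combination appearing exactly R times.
* **Phylogeny**: pure-birth (Yule) topology with independent exponential
  branch lengths — the simplest process giving strictly positive branch
  lengths — tips labelled `ASV_1..n`.
* **Communities**: a shared lognormal metacommunity (log-sd 2.5, chosen so
  that occupancy at the default depth of 10,000 reads sits in the 60–85%
  range typical of ASV tables rather than at 100%, which would make
  nearest-taxon turnover degenerate). In selection mode a Brownian-motion
  trait evolves on the tree and each sample filters the metacommunity
  through a Gaussian niche $\exp(-(trait-env)^2/2\sigma^2)$ whose width is
  $\sigma = sd(trait)/filtering\_strength$ — scaling by the realized trait
  spread makes a given strength mean the same selective pressure on any
  simulated tree. Vegetation-season groups receive optima at evenly spaced
  trait quantiles, so groups at opposite ends are environmentally
  contrasting. Neutral mode applies no filter; both modes share the same
  code path (and random-number stream), so selection with
  `filtering_strength = 0` reproduces the neutral output exactly. Samples
  mix the filtered metacommunity with a Dirichlet-perturbed local copy
  (`dispersal` sets the mixing weight, default 0.8) and counts are
  multinomial at the configured depth, so rows always sum to the depth.
* **Function matrices**: 20 variables with distinct baselines, Gaussian
  noise (sd default 1), and a uniform raw-scale autumn deficit (default
  1.5), reproducing the qualitative summer-over-autumn multifunctionality
  contrast.
* **Planted correlations**: lognormal basis abundances with a target
  log-scale correlation matrix, closed to compositions and multinomially
  sampled. If the planted entries make the matrix indefinite it is
  projected to the nearest positive semi-definite correlation matrix by
  eigenvalue clipping, and the projection is recorded in an attribute.

What the generator does **not** emulate: sequencing error and chimeras,
taxonomy, variable library sizes, overdispersion beyond multinomial
sampling, phylogenetic signal in abundances independent of the environment
filter, and temporal autocorrelation between seasons. Passing tests
therefore demonstrate that the estimators recover planted structure under
clean sampling assumptions — not that field data meet those assumptions.

## Numerical choices and problem sizes

* All Monte-Carlo routines take an explicit integer seed; the pipeline
  derives per-stage substreams from one master seed so adding a stage never
  perturbs another stage's draws. RNG state is restored on exit.
* Permutation p-values always carry the +1 correction; ties in permutation
  statistics are counted as "at least as extreme" with a $10^{-12}$
  tolerance.
* beta-NTI marks null standard deviations below $10^{-12}$ as degenerate.
* SparCC basis variances are floored at $10^{-10}$ before the square root.
* The test suite runs assembly recovery at 60 taxa x 24 samples x 199
  nulls (20 paired selection/neutral runs), SparCC recovery at 15–20 taxa
  x 60–80 samples over 50 runs, and calibration at 200–400 null
  simulations; the acceptance script runs the full pipeline at 100 taxa x
  96 samples with 199 assembly nulls, 999 test permutations and 100
  bootstraps. These sizes were chosen to keep a complete desk run in
  minutes while leaving every estimate's Monte-Carlo error well inside the
  margins the checks assert.

## Known limitations

* The one-factor PERMANOVA cannot adjust one factor for another; apparent
  treatment effects in unbalanced subsets should be checked against the
  balanced design.
* SparCC's sparsity assumption fails when most pairs are truly correlated
  (e.g. one dominant environmental gradient); in that regime correlations
  are attenuated but networks remain dense, as the simulated seasonal
  gradient illustrates.
* RCbray's null preserves richness and total abundance but not
  within-sample aggregation; over-dispersed field counts will make the null
  narrower than the data.
* The five-process classification inherits the fixed thresholds' coarse
  granularity; values near $|\beta NTI| = 2$ or $|RC| = 0.95$ flip class
  with small resampling noise.
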