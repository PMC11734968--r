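---
title: "Mixed graphical model networks of well-being: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed graphical model networks of well-being: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wellnet)
```

wellnet implements a cross-sectional network analysis for psychometric data
of mixed domains: continuous construct scores (well-being, quality of life,
coping, perceived stress, ...) together with categorical history variables
(e.g. disease categories). The analysis treats the variables as nodes of a
pairwise Markov random field and asks which pairs remain associated after
conditioning on everything else, how stable those associations are under
resampling, how the network organises into (possibly overlapping)
communities, and which nodes stabilise a community from within or
communicate across communities.

This vignette documents the models, the tunable parameters, the synthetic
data generator used for validation, and the places where the design was
genuinely open and a choice had to be made.

## The pairwise mixed graphical model

For variables $X_1, \dots, X_p$ of mixed domains we estimate a pairwise
Mixed Graphical Model (MGM) by nodewise neighborhood selection: every node
is regressed on all remaining variables with an $\ell_1$ penalty — a linear
model for Gaussian nodes, a multinomial logistic model for categorical
nodes. Nonzero coefficients define candidate edges; two nodes are
conditionally independent when they are not directly connected.

* Continuous variables are standardized before fitting and categorical
  predictors are dummy-coded against their first level, so edge weights are
  comparable across variable pairs (they behave like partial correlations
  for continuous–continuous pairs).
* The penalty path holds 50 log-spaced values from $\lambda_{\max}$ (the
  smallest penalty with an all-zero fit, as constructed by glmnet) down to
  $0.01\,\lambda_{\max}$.
* The penalty is selected per regression by the Extended Bayesian
  Information Criterion
  $\mathrm{EBIC} = -2\,\ell + \mathrm{df}\,\log n + 2\gamma\,\mathrm{df}\,\log q$,
  with $\mathrm{df}$ the nonzero coefficient count, $q$ the number of
  candidate terms, and the conservative $\gamma = 0.25$ as default. Ties are
  broken toward the larger penalty (the sparser model). The degrees of
  freedom count nonzero coefficients directly; no refitting is done.
* The two directed regressions of a pair are combined by the AND rule: an
  edge exists only when both regressions retain it, and its magnitude is
  the mean of the two directed magnitudes (each the mean absolute value of
  all coefficient terms linking the pair — several terms when categorical
  levels are involved). An OR variant is available. An edge sign is defined
  only for continuous–continuous pairs whose coefficients agree in sign;
  edges involving a categorical variable are unsigned.

The AND rule and the coefficient-count df convention are not forced by the
method; they are the classic neighborhood-selection choices and are
documented and configurable (`rule`, `gamma`, `nlambda`,
`lambda_min_ratio`).

```{r}
sim <- study_mimic(seed = 1)
fit <- fit_mgm(sim$data)         # gamma = 0.25, AND rule
tidy(fit)                        # signed weighted edge list
```

## Edge stability and nodewise predictability

`bootstrap_stability()` quantifies edge stability by the nonparametric
bootstrap: rows are resampled with replacement (default $B = 1000$; scale
down for exploration), the full estimation — including re-standardization
and per-resample penalty selection — is repeated, and each node pair is
summarized by its nonzero proportion, an empirical quantile interval
(default level 0.95), and a stability class: *very stable* above 0.90,
*relatively stable* in $(0.85, 0.90]$, otherwise *unstable*. The band
endpoints are ambiguous in prose descriptions ("more than 90%", "between
85% and 90%"); here the boundary 0.90 belongs to the lower band. Pairs
absent from the full-data network still receive bootstrap statistics and
are flagged. A resample in which a continuous column degenerates to zero
variance is redrawn and counted.

`predictability()` reports how well each node is predicted by its selected
neighborhood: in-sample $R^2$ for continuous nodes, in-sample accuracy next
to the marginal-mode baseline for categorical nodes. In-sample values match
the "proportion of explained variance" reading; they are optimistic
relative to cross-validated ones, which matters little at $n \gg p$.

## Overlapping communities by weighted clique percolation

Communities are detected on the unsigned magnitude graph. A $k$-clique is
admitted when its *intensity* — the geometric mean of its edge magnitudes —
reaches the threshold $I$ (closed comparison, $\ge I$); two $k$-cliques are
adjacent when they share $k - 1$ nodes; communities are the node unions of
the connected components of that clique graph. Nodes can belong to several
communities (cross-loading); nodes in none are isolated. Signs are ignored
because percolation operates on association strength, and unsigned
(categorical-involving) edges participate with their magnitudes.

`threshold_grid()` evaluates all combinations of $k \in \{3, 4\}$ (3 is the
smallest size the algorithm admits) and $I \in \{0, 0.005, \dots,
\max |w|\}$. The step 0.005 resolves optima reported to three decimals.
Two indicators guide the choice of $(k, I)$:

* **Ratio.** The ratio of the largest to second-largest community size
  marks the emergence of a giant component. We operationalize "just above
  the emergence point" as the *smallest* multi-community threshold at which
  the ratio first comes down to 2. Scanning upward from $I = 0$ the largest
  community shrinks; the first grid row with at least two communities and
  ratio $\le 2$ is the ratio candidate. Rows with a single community have
  ratio $\infty$ (always a giant component) and cannot mark a crossing. An
  alternative reading — the largest threshold with ratio $\ge 2$ — proved
  degenerate in testing: far beyond the crossing, crumbling covers (e.g. a
  4-node and a 1-clique-wide community) satisfy it spuriously.
* **Entropy.** The Shannon entropy of the effective community sizes, where
  shared nodes are split equally among their communities and all isolated
  nodes are pooled into one pseudo-community. Entropy prefers many
  similar-sized communities with little isolation; the grid row maximizing
  it is the entropy candidate (ties toward the first row in $(k, I)$
  order). `permute_entropy_null()` calibrates it: each permutation
  re-places the observed edge magnitudes uniformly over node pairs
  (preserving edge count and the weight multiset, not degrees), the maximal
  entropy over the grid is recorded per $k$, and the 97.5th percentile of
  those maxima is the 95% upper bound.

A caution on the entropy null: for dense, block-structured networks the
permuted graphs fragment at intermediate thresholds into many small
communities plus an isolated pool — configurations this entropy rewards —
so an observed block cover need not exceed the null band even when it is
exactly right. The null is most informative for sparse networks, where
random rewirings produce few triangles. The ratio indicator does not suffer
from this.

`select_solution()` codifies the final choice (described in the source
analyses as visual inspection) as a deterministic rule. Between the two
candidates it prefers, in order: (1) a largest community holding at most
50% of the non-isolated nodes (no giant component), (2) fewer isolated
nodes, (3) more communities, (4) higher entropy; remaining ties go to the
ratio candidate. Every comparison is recorded in a rationale so the
decision stays auditable.

## Local structure: stabilizing and communicating indices

For node $v$ in community $c$, the *stabilizing index* sums the absolute
magnitudes of $v$'s edges to co-members of $c$, and the *communicating
index* sums those to members of other communities. Edges to isolated nodes
count toward neither (they connect to no community), and their omitted
strength is visible by comparing against total node strength. Cross-loading
nodes get one row per community. Absolute magnitudes are summed because the
published index tables contain no negative entries; signed summation is
available behind `signed = TRUE`. Within each community the top two
stabilizers/communicators are flagged, extended to a third when it lies
within 0.05 of the second — an explicitly arbitrary display convention,
configurable via `tie_window`.

`subscale_network()` re-estimates an MGM for one community with
multi-dimensional constructs replaced by their subscale columns. Community
networks estimated in isolation change with the variable set and will not
exactly reproduce the full network's weights. Exported views hide edges not
stronger than 0.05 (`display_edges()`); the full table keeps them.

## Moderated network models

`fit_moderated()` augments every nodewise regression with product terms
$x_j x_m$ for one user-named continuous moderator $m$, selecting by EBIC as
usual. Moderation magnitudes are aggregated across the two involved
regressions by the same mean-of-absolutes and AND convention; the
moderator's own row is structurally zero. Categorical moderators are not
supported.

## The synthetic-data generator

Because the motivating study's raw data are not deposited, every stage is
validated against generated data with known ground truth.

`make_planted_model()` plants a block-structured pairwise model: all
within-community pairs get the requested interaction magnitude, a sparse
set of between-community pairs (one per community pair) gets a weaker one,
isolated nodes get none, and roughly 25% of planted edges are negative,
mirroring the mixed-sign networks of real psychometric data. For
all-continuous models the implied precision matrix is $I - \Theta$. Equal
partial correlations $\rho$ inside a block of $m$ nodes are only feasible
for $\rho < 1/(m-1)$; infeasible requests are repaired by uniform diagonal
loading, implemented as a uniform shrink of all interactions that keeps the
smallest eigenvalue at 0.05 and preserves the within/between contrast
exactly (the `repair_factor` is reported on the model). When the request is
feasible no shrink occurs and realized partials equal the requested
weights.

`sample_mgm()` draws all-continuous models exactly from the implied
Gaussian, rescaled to unit marginal variances (partial correlations are
invariant under this diagonal scaling) and then de-standardized to the
declared means/SDs. Models with categorical nodes are sampled by a
vectorized Gibbs sweep over the full conditionals — linear-Gaussian with
unit conditional variance for continuous nodes, multinomial-logistic over
centered level scores for categorical nodes — run as one independent chain
per observation with 200 burn-in sweeps (sequential node order, logged).
Doubling the burn-in changes pairwise summaries by less than Monte-Carlo
noise in the test suite. Planted three-way terms enter the conditionals of
the two moderated nodes as products with the moderator; the moderator
itself is sampled exogenously and updated first in each sweep, because a
symmetric cubic potential is unnormalizable (its density diverges in the
all-positive octant). States are clamped at $\pm 8$ conditional SDs as a
numerical guard; under the default settings the clamp is never hit.

`study_mimic()` generates the 30-variable study emulation: 28 continuous
constructs calibrated to the published means and SDs (e.g. mental
well-being 55.6/5.88, quality of life 94.7/9.46), one 8-level and one
3-level categorical variable with fixed marginal frequencies, $n = 2000$.
The planted dependence structure follows the published community-size
template — five communities of sizes 12, 6, 6, 4, 4 — implemented as
chained blocks overlapping in four single cross-loading nodes over the 28
continuous constructs, with the two categorical variables isolated.
Single-node overlaps keep the planted cover identifiable under $k = 3$
percolation: blocks sharing $k - 1 = 2$ nodes would merge into one
community by construction. Requested weights default to 0.3 within and 0.05
between; after the positive-definiteness repair (factor $\approx 2.5$ under
the default seed) realized within-block partials are $\approx 0.12$, which
at $n = 2000$ puts single-edge detection in a realistic, not saturated,
power regime. The generator does not emulate item-level responses,
skewness, floor/ceiling effects, or time-varying covariates — so passing
recovery tests demonstrate correctness of the machinery under the assumed
model class, not robustness to those real-data features.

```{r}
bundle <- run_pipeline(default_config(
  seed = 1,
  bootstrap = list(B = 100, level = 0.95)
))
bundle$selection
```

## Numerical choices and degenerate inputs

* MAD outlier rule: robust z-score $|x - \mathrm{med}| / (1.4826\,
  \mathrm{MAD})$ with threshold 2.5. The constant makes the MAD consistent
  for the SD under normality. A zero MAD carries no outlier information:
  nothing is flagged and a warning is emitted.
* Exclusion rules run sequentially in declared order, each counted against
  the survivors of earlier rules, as participant-flow diagrams report them.
* Zero-variance continuous columns abort standardization with the column
  named; degenerate bootstrap resamples are redrawn and counted.
* Quantile intervals use the default empirical quantile (type 7).
* glmnet solves to its default tolerance; permuting dataset columns changes
  weights only at that tolerance (the sparsity pattern is invariant).
* Categorical levels declared but unobserved yield all-zero dummies, which
  the penalty never selects.

## Problem sizes in the test suite

The suite validates on deliberately modest sizes chosen to exercise every
code path with stable Monte-Carlo margins: the 30-node mimic at $n = 2000$
with $B = 100$ bootstrap resamples and 100 entropy permutations; estimator
oracles at $p = 10$, $n = 5000$ over 20 seeds; brute-force percolation
cross-checks on 100 random networks of up to 10 nodes; moderation power and
null runs at $n = 5000$ and $n = 2000$. The study-scale defaults
($B = 1000$) remain the package defaults.

## Known limitations

* In-sample predictability is optimistic; use the optional refit on held
  out data for honest out-of-sample numbers if needed.
* The permutation scheme for the entropy null destroys degree structure;
  degree-preserving rewiring is a possible alternative and the scheme is
  isolated in one function so it can be swapped.
* Moderation supports a single continuous moderator per run; categorical
  moderators and higher-order interactions are out of scope.
* Community-restricted subscale networks are estimated in isolation and do
  not quantify how subscales relate to nodes outside the community.
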