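---
title: "Feature selection with multiple kernel learning: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature selection with multiple kernel learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smklfs)
```

## The problem

Two-class expression studies — tumour against matched adjacent-normal tissue
being the canonical design — produce matrices with thousands of features
(genes, miRNAs) and a few dozen samples. Most features are irrelevant to the
class; many of the relevant ones are redundant copies of each other through
co-regulation. The goal of this package is to produce a *compact* feature
subset that separates the classes, together with honest measurements of how
good and how stable that subset is.

## The model

### SVM dual and the MKL objective

For samples $x_i$ with labels $y_i \in \{+1,-1\}$ and a kernel $K$, the
soft-margin SVM dual is

$$
W(\alpha) = \max_{\alpha}\; \sum_i \alpha_i
 - \tfrac12 \sum_{i,j} \alpha_i \alpha_j y_i y_j K(x_i, x_j)
\quad\text{s.t.}\quad \sum_i \alpha_i y_i = 0,\; 0 \le \alpha_i \le C .
$$

Multiple kernel learning replaces the single kernel with a convex
combination $K = \sum_{m=1}^M d_m K_m$, $d_m \ge 0$, $\sum_m d_m = 1$, and
learns the weights jointly with the classifier. The quantity this package
is organized around is the saddle-point value

$$
J \;=\; \min_{d \in \Delta}\; \max_{\alpha}\; W(\alpha, d),
$$

the best (smallest) achievable dual optimum over the weight simplex
$\Delta$. A small $J$ means some convex combination of the base kernels
supports a wide-margin separation; $J$ therefore acts as a relevance score
for whatever feature set the kernels were computed on.

### The two-stage selection algorithm

**Stage 1 (relevance ranking).** For each feature alone, build the bank of
base kernels on that one feature and solve for $J$. Sort ascending: the
smaller the single-feature $J$, the more that feature supports separation.
Keep the top $n^{*}$ features. Zero-variance features receive $J = \infty$
and sort last instead of raising an error, because real expression matrices
contain them.

**Stage 2 (forward subset search).** Starting from $Z = \varnothing$ with
$J_0 = +\infty$, each round computes $J_{Z \cup \{f\}}$ for every remaining
candidate $f$ and accepts the one with the largest reduction
$\Delta J = J_{\text{prev}} - J_{Z \cup \{f\}}$, stopping when
$\Delta J \le 0$, when $|Z| = r_{\max}$, or when candidates run out. Because
maximizing $\Delta J$ is minimizing $J_{Z\cup\{f\}}$, the first round
automatically picks the stage-1 winner. A feature whose marginal
contribution duplicates what $Z$ already encodes (a redundant co-regulated
copy) produces a small or negative $\Delta J$ and is passed over — this is
what eliminates redundancy without any explicit correlation screen.

Rejected candidates are never revisited in later rounds (standard
sequential forward selection). This is an interpretation: the alternative
of re-admitting previously rejected features would make runs quadratically
more expensive and can oscillate; never-revisit keeps the trace strictly
decreasing in $J$ by construction.

`skip_stage1 = TRUE` runs the forward search over all features directly.
Round-one ties then break by feature order in the input matrix, since there
are no stage-1 ranks to break them.

## Solving the saddle point

### Inner problem

At fixed weights $d$ the inner problem is a convex box-constrained QP with
one equality constraint. It is solved by a primal–dual interior-point
method with a Mehrotra predictor–corrector step (`solve_box_qp()`). The
box-plus-single-equality structure reduces every Newton step to one
Cholesky factorization of $H + D$ with $D$ diagonal positive, which also
regularizes rank-deficient Hessians (e.g. a linear kernel on one feature)
without an explicit ridge. Iteration stops when the duality gap falls below
`1e-10` relative to the objective scale; on positive-definite instances the
solver agrees with an independent interior-point implementation to better
than $10^{-5}$ in $\alpha$. When the dual Hessian is rank-deficient the
maximizing $\alpha$ need not be unique — only the objective value is; tests
therefore compare $\alpha$ across solvers only on strictly positive
definite Grams.

### Outer descent on the simplex

The envelope theorem gives the gradient of the inner optimum in the
weights at the maximizing $\alpha$:
$\partial J / \partial d_m = -\tfrac12 \alpha^\top (y y^\top \circ K_m)\,\alpha$.
The descent direction is the negative reduced gradient with the largest
$d_m$ as the reference coordinate, projected so that coordinates at zero
whose reduced gradient points outward stay at zero; the direction sums to
zero, keeping iterates on the simplex. The line search starts at the step
that reaches the nearest simplex face and halves up to 20 times until the
objective strictly decreases; if no step decreases it, the current point is
declared stationary. Only improving steps are ever taken, so $J$ is
non-increasing across outer iterations by construction. The loop ends when
the relative change in $J$ drops below `dual_gap_tol` (default `1e-3`) or
after `max_outer_iter` (default 200) iterations; non-convergence is
reported in the model object (`converged = FALSE`), not raised as an error.

Weights start uniform at $1/M$, which makes runs deterministic. With
identical base kernels the weights are indeterminate (any simplex point
gives the same combined kernel); tests assert the objective, never the
weights, in such degenerate cases.

### Ties and degenerate cases

* Ranking ties (equal $J$) break by input feature order; forward-search
  ties break by lowest stage-1 rank. Both rules make runs bit-reproducible.
* `sign(0)` in prediction maps to $+1$ — arbitrary but fixed.
* Support vectors are reported at the threshold $\alpha_i > 10^{-8} C$.

## Kernels and their preparation

The default bank is the three-kernel combination used throughout: linear
$\langle x_i, x_j\rangle$, RBF $\exp(-\lVert x_i - x_j\rVert^2 / 2)$, and
inhomogeneous polynomial $(\langle x_i, x_j\rangle + 1)^2$. The RBF is
parameterized as $\exp(-\lVert\cdot\rVert^2 / (2\sigma^2))$ with
$\sigma^2 =$ `rbf_bandwidth`, so the default bandwidth of 1 gives the
denominator 2 of the default bank.

Two preparation steps are on by default and disabled by flags:

* **Per-feature z-scoring** (statistics fit on training samples only).
  RBF distances and polynomial inner products are scale-sensitive;
  without standardization a feature's ranking would depend on its
  measurement units. This also makes the stage-1 ranking invariant to
  feature-wise affine rescaling.
* **Trace normalization** of each base Gram to trace $n$. The three
  families produce matrices on wildly different scales (a degree-2
  polynomial kernel on a z-scored feature has diagonal entries up to
  $(x_i^2+1)^2$); without a common scale one family dominates the convex
  combination for reasons of units, not information.

Stage-2 candidate Grams are built from additive per-subset accumulators
(the inner-product matrix and the squared-distance matrix are both sums of
per-feature contributions), so evaluating $Z \cup \{f\}$ is a rank-style
update rather than a recomputation. The tests verify the incremental route
equals full recomputation to $10^{-8}$ through the resulting objectives.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `C` | 1 | soft-margin cost; bounds every $\alpha_i$ |
| `dual_gap_tol` | 1e-3 | relative $J$ change that stops the outer loop |
| `max_outer_iter` | 200 | cap on outer iterations |
| `qp_tol` | 1e-8 | inner-QP accuracy (duality-gap scale) |
| `n_star` | 100 | stage-1 list size (matches the usual stability/similarity list length) |
| `r_max` | 10 | stage-2 subset cap (matches top-10 effectiveness tables) |
| `rbf_bandwidth` | 1 | RBF denominator is `2 * rbf_bandwidth` |

## Preprocessing chain

The chain is fixed as **filter → impute → merge → normalize**; the order
matters (merging maxima before normalizing is not the same as the reverse,
and the tests demonstrate the difference).

* **Missingness filter.** "Fewer than 20% missing" is read strictly:
  probes with missing fraction $\ge 0.20$ are dropped.
* **Local least squares imputation.** Each missing entry is predicted by
  regressing the target probe on its `neighbor_count` (default 10) most
  correlated *complete* probes over the target's observed samples.
  Neighbor choice is by absolute Pearson correlation. The regression
  includes an intercept, which costs nothing when probes are linearly
  dependent and guards against pure level shifts; a constant target is
  filled with its constant directly. If fewer complete probes exist than
  `neighbor_count`, the affected probe falls back to a row-median fill
  with a warning.
* **Probe merging.** Probes of the same gene merge by the per-sample
  maximum.
* **MAD normalization.** Per *sample* (column): subtract the median,
  divide by the raw median absolute deviation — no 1.4826 Gaussian
  consistency constant. The constant would cancel in the downstream
  kernels anyway once z-scoring is on; the point of the step is
  equalizing sample backgrounds, not estimating a Gaussian scale. A
  per-feature mode exists behind `margin = "feature"`.

## Evaluation harness

* **Effectiveness.** For a nested chain $S_1 \subset \cdots \subset S_n$
  (default length 10), the per-$k$ value is stratified 10-fold CV accuracy
  of a classifier trained on $S_k$; the mean and max over $k$ summarize
  the chain. The classifier defaults to the MKL predictor with the default
  bank; `classifier = "linear"` uses a single linear-kernel SVM and is
  much faster. Accuracy is averaged over folds within a resample group
  first, then over groups, and the report says so.
* **Stability.** $k$ subsamples (default 10) each drawing 90% of the
  *pairs* without replacement; union stability is
  $|\cap_i S^i| / |\cup_i S^i|$ and independent stability the mean
  pairwise Jaccard index. A pair of sets with an empty union contributes 0
  with a warning (unreachable for fixed-size nonempty lists).
* **Similarity.** The mean intersection *size* (not Jaccard) between one
  method's list and other methods' lists of the same length; external
  lists are read from one-feature-per-line text files.
* **Folds and pairs.** CV folds are stratified by class, and a pair's two
  samples always land in the same fold — splitting a tumour sample from
  its matched normal would leak subject-level information.

## The synthetic generator

`simulate_expression()` plants known structure so every claim above is
testable without downloads: informative features are Gaussian with class
means $\pm\Delta/2$ (in units of the within-class standard deviation),
redundant features mix a standardized parent with fresh noise so their
population correlation with the parent is exactly $\rho$ (the parent is
standardized *including* its class shift before mixing — mixing the raw
parent would inflate the realized correlation above $\rho$), irrelevant
features are pure noise, and samples come in tumour/normal pairs that can
share a random intercept. A log-scale mode exponentiates values to mimic
the positivity of raw intensities for preprocessing tests.

Default conditions — 30 pairs, 200 features, 10 informative at
$\Delta = 2$, 10 redundant at $\rho = 0.9$ — are the reference conditions
used by the test suite and the acceptance script: small enough to run on a
laptop core in minutes, hard enough that ranking by a naive univariate
statistic and by the MKL objective genuinely differ in stage 2 (the
redundant copies rank high in stage 1 but are passed over by the forward
search once their parent is in $Z$).

What the generator does **not** emulate: count noise of RNA-seq
(negative-binomial mean–variance structure), batch effects, heavy-tailed
intensity distributions, or correlated noise blocks beyond the planted
parent–copy pairs. Passing the planted-recovery tests therefore
demonstrates correctness of the algorithmic machinery under the stated
Gaussian model, not performance claims about any particular real cohort.

## Known limitations

* Two classes only; no multi-class extension of the objective.
* The stage-1 scan is embarrassingly parallel but currently serial; at
  desk scale (hundreds of features, tens of samples) a full run is
  seconds, but genome-scale matrices should be pre-filtered or run with
  `skip_stage1 = FALSE` and patience.
* `J` depends on `C` and on the kernel bank; rankings are comparable only
  within one configuration.
* The forward search is greedy: it inherits the usual sequential-selection
  blindness to complementary pairs whose individual $\Delta J$ is
  non-positive.

## A worked run

```{r worked}
ds <- simulate_expression(synthetic_spec(n_pairs = 30, p = 200,
                                         k_informative = 10, k_redundant = 10,
                                         effect = 2, seed = 1))
fit <- smkl_fs(ds, n_star = 20, r_max = 10)
head(fit$scores)
tidy(fit$trace)
dplyr::left_join(tidy(fit$trace), attr(ds, "roles"), by = "feature_id")[, c("step", "feature_id", "role")]
```

The selected subset is dominated by planted informative features; redundant
copies score well in stage 1 but are rarely accepted in stage 2, because
adding a near-copy of something already in $Z$ barely reduces $J$.
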