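---
title: "Local hyperplane discriminant analysis: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local hyperplane discriminant analysis: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-dimensional labelled data — gene-expression matrices above all — mix a
handful of informative features with thousands of irrelevant ones. Distance
-based classifiers degrade quickly in that regime, and filter-style feature
scores ignore the classifier they are meant to serve. `lhda` couples the two
decisions: it learns a nonnegative per-feature weight vector *through* the
classifier whose accuracy the weights are supposed to improve, so feature
selection and classification are optimised together.

## The model

All geometry happens in a feature-weighted Manhattan metric
$d(p, q) = \sum_j w_j |p_j - q_j|$, $w_j \ge 0$.

**Classification (FHKNN).** For a query $x$ and each class $c$, take the $k$
nearest same-class training points $h_1, \dots, h_k$ under $d$, and form the
*local hyperplane* — the set of simplex combinations $H\alpha$,
$\sum_i \alpha_i = 1$, $\alpha \ge 0$. The class distance is the projection
problem

$$J(\alpha \mid w) = \min_\alpha \; w^T\,|x - H\alpha|,$$

and the predicted label is the class with the smallest projected distance.
The simplex constraint keeps the hyperplane inside the convex hull of the
neighbours, so an outlying neighbour cannot extrapolate the class towards
the query.

**Feature weighting.** For every training sample $x_i$, build two
hyperplanes: the *nearest hit* (its own class, with $x_i$ itself excluded —
leave-one-out semantics) and the *nearest miss* (the closest foreign class).
Their distance ratio $R(x_i) = d_{NH} / d_{NM}$ is below 1 exactly when the
hyperplane rule classifies $x_i$ correctly. The 0/1 error indicator is
smoothed by a sigmoid with slope $\beta$,
$S_\beta(z) = 1/(1 + e^{\beta(1 - z)})$, giving the penalised objective

$$J(w) = \frac{1}{N}\sum_i S_\beta(R(x_i)) + \lambda \lVert w \rVert_1 .$$

Nonnegativity is structural: with $v^2 = w$ the l1 penalty becomes the
smooth $\lambda \lVert v \rVert_2^2$ and the gradient takes the Hadamard
form $(2\lambda \mathbf{1} + \tfrac{2}{N}\Upsilon^T G) \otimes v$ with
$\gamma_i = S'_\beta(R_i) R_i$ and
$g_i = |x_i - s_{NH}|/d_{NH} - |x_i - s_{NM}|/d_{NM}$. Weights are never
clipped.

## The algorithm

`lhda_fit()` alternates, in the spirit of expectation–maximisation:

1. **Re-estimation.** Under the current $w$, rebuild every sample's NH/NM
   neighbour sets, spanning coefficients and distances.
2. **Descent.** Take a gradient step on $v$, backtracking (halving the step
   up to 30 times) until the objective *with hyperplanes and coefficients
   frozen* does not increase. On the frozen surface the analytic gradient is
   exact, which is also what the finite-difference tests verify.

Iteration stops when the l1 change of the *normalised* weight profile falls
below `tol`, or after `max_iter` iterations. The profile criterion is
deliberate: margins and predictions are invariant to the scale of $w$, and
the l1 penalty keeps shrinking that scale indefinitely, so a stopping rule
on the raw change in $w$ would either fire too early (absolute) or never
(relative to a shrinking norm).

### Why the trace can tick upward

The per-step line search guarantees that the frozen-surface objective never
increases (`objective_frozen` in the trace, checked against the previous
objective by the tests). The *fresh* objective after re-estimation
(`objective` in the trace) is usually non-increasing too, but not always:
neighbour sets switch discretely as $w$ moves, and the margin is a ratio, so
re-optimising both the hit and the miss hyperplane can raise $R$ for some
samples. No step-size control can remove these jumps — the fresh objective
is genuinely discontinuous in $w$. Enforcing monotone fresh descent was
tried and stalls the alternation after a handful of iterations, destroying
weight recovery; the frozen-surface rule is the one the algorithm needs.

### The spanning-coefficient solve

The projection $\min_\alpha w^T|x - H\alpha|$ over the simplex is a small
linear program. The default (`solver_mode = "exact"`) reduces it to an
affine weighted least-absolute-deviations fit (Barrodale–Roberts, via
the quantreg package); when the affine optimum leaves the simplex, convexity
places the constrained optimum on a facet, which is searched recursively
down to edges solved in closed form by weighted medians; a vertex bound
guards the solution. The tests verify the solve against an exhaustive
simplex-grid enumeration. The alternative `solver_mode = "surrogate"`
minimises the linear upper bound $\alpha^T z$, $z_i = w^T|x - h_i|$; a
linear function on a simplex attains its minimum at a vertex, so the
surrogate always collapses the hyperplane onto the single nearest neighbour
(ties split uniformly). It is kept for fidelity to the linearised
formulation, but the exact mode is the default because it realises the
stated objective and preserves the point of a hyperplane.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 3 | neighbours per hyperplane; small values keep the locality assumption honest and the cost linear |
| `lambda` | 0.01 | l1 penalty. The margin term lives in $[0,1]$ and $\lVert w\rVert_1 = 1$ at initialisation, so `lambda` is the fraction of the margin term's range the penalty occupies at the start. Values near 1 let the penalty dominate and crush informative weights along with the noise (verified on the spiral benchmark); 0.01 applies gentle, persistent sparsity pressure |
| `beta` | 5 | sigmoid slope; moderate values keep gradients informative across the whole margin distribution instead of only at the decision boundary |
| `eta` | 0.1 | initial step size; uncritical because of backtracking |
| `max_iter` | 300 | the alternation needs a few hundred iterations to bootstrap the metric when irrelevant features outnumber informative ones; runs on clean data converge far earlier via `tol` |
| `tol` | 1e-4 | l1 change of the normalised weight profile |
| `ratio_cap` | 1e6 | finite stand-in for an infinite margin ratio when $d_{NM} = 0$; at any reasonable `beta` the sigmoid is fully saturated there, so the exact value is immaterial |

Degenerate margins are defined rather than left to chance: $d_{NM} = 0$
with $d_{NH} > 0$ gives $R = $ `ratio_cap`; both distances zero give
$R = 1$; a zero hyperplane distance inside a gradient term contributes the
zero vector. Neighbour ties break by ascending sample index, class-distance
ties by the smallest class label — the learner is fully deterministic given
the data; the only randomness in the package sits in data generation and
fold assignment, both seedable.

## The spiral benchmark

`spiral_data()` draws two interleaved Fermat arms ($r = \sqrt\theta$,
$\theta$ uniform on $[0.25, 4\pi]$, the second arm point-reflected) plus any
number of i.i.d. standard-normal noise features. Labels depend only on the
first two features, so the generator gives a ground truth for weight
recovery: a correct learner must push the noise weights to (near) zero.

Two generator choices deserve comment:

* **Scale.** By default the informative features keep their raw spiral
  scale (standard deviation ≈ 1.8 over the default angle range) against
  unit-variance noise. The `standardize` flag equalises the scales, but
  doing so also makes the two arms' *marginal* distributions in the
  informative features identical (one arm is the point reflection of the
  other), which removes the averaged hit/miss asymmetry the first
  iterations rely on when neighbour selection is still noise-dominated —
  weight recovery then fails at any appreciable noise dimension. The raw
  scale is both the classic setup and the one under which the benchmark is
  informative.
* **Reliability is part of the result.** At 100 noise dimensions the
  learner recovers the informative pair and suppresses ≥ 90 % of the noise
  weights in most seeded runs, but individual runs can lock onto noise
  structure and fail — the acceptance checks therefore demand success in 2
  of 3 seeded repeats, not in every run. Beyond roughly 150–200 noise
  dimensions failures become common at this sample size (200 per class);
  runs that do recover classify at ≈ 96 % leave-one-out accuracy, runs
  that do not fall to ≈ 70 %.

What the generator does *not* emulate about real expression data: feature
correlations (noise features are independent), heavy tails and batch
structure, and class imbalance. Passing the spiral checks shows the margin
machinery and the sparsity mechanism work; it does not promise the same
recovery rates on correlated biological noise.

## Evaluation protocols

`lhda_loocv()` and `lhda_kfold()` score a *fixed* weight vector, mirroring
the common protocol of learning weights once and then evaluating classifiers
in the weighted space; the weight learning itself is leave-one-out in its
margins, but information from every sample (including a later test sample)
enters the weights. The honest, leakage-free protocol is
`lhda_inner_loocv()`, which re-learns the weights from scratch inside every
split — the tests verify that perturbing a held-out sample cannot change
that split's weights. Ten-fold splits are stratified by class (per-class
fold sizes differ by at most one) because at microarray sample sizes an
unstratified split regularly starves a fold of one class; `stratify =
FALSE` restores the plain protocol and, with `folds = N`, reproduces
leave-one-out exactly.

The `ttest_prefilter()` uses the classic pooled-variance two-sample test
(the unqualified "t-test" of the microarray era; Welch is available via
`var_equal = FALSE`). Features that are constant and identical in both
classes have no defined statistic and are dropped.

## Problem sizes used in the automated checks

The packaged checks run the full pipeline on spirals of 200 samples per
class with noise dimensions up to 200 and three repeats per setting —
twelve weight-learning runs plus their leave-one-out and ten-fold
evaluations — and verify the solver, gradient and protocol properties on
batches of 20–100 small random instances. These sizes were chosen so the
entire suite completes on a single CPU in well under half an hour while
still exercising the regime (hundreds of samples, low-hundreds of features)
where the method's behaviour changes qualitatively.

## Known limitations

* Weight learning is a nonconvex alternation; it has no global-optimality
  guarantee, and at high noise-to-signal ratios different seeds can reach
  qualitatively different weight profiles (see above).
* The objective is discontinuous at neighbour-set switches; convergence is
  declared on the weight profile, not on a vanishing gradient.
* One fitting iteration costs $O(c\,k\,N\,D)$ for the hyperplane pass plus
  $O(N\,D)$ for the update, with the simplex projections on top; the method
  targets hundreds-to-thousands of samples, not millions.
* Multiclass problems are handled by taking the nearest-miss over all
  foreign classes; the t-test prefilter is two-class only by construction.
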