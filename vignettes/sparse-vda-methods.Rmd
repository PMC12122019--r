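---
title: "Sparse vertex discriminant analysis: model, solver, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse vertex discriminant analysis: model, solver, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsevda)
```

## The model

Vertex discriminant analysis (VDA) handles `c` classes in a single model by
encoding class `j` as the standard basis vector `e_j` of `R^c` — the vertices
of a regular simplex, any two a distance `sqrt(2)` apart. A linear map
`x -> t(B) x + b0` predicts a point in vertex space and a sample is assigned to
the nearest vertex. Training minimizes the squared epsilon-insensitive risk

    f(B) = (1/2n) * sum_i max(0, ||y_i - t(B) x_i|| - epsilon)^2,

so residuals within a Euclidean ball of radius `epsilon` around the class
vertex are loss-free, which gives the classifier a support-vector flavor while
staying differentiable. The deliberately overparameterized encoding (`c`
columns rather than `c - 1`) keeps one coefficient column per class; this is
what makes *class-specific* variable selection expressible as a constraint on
columns of `B`.

Variable selection is imposed through constraint sets rather than shrinkage
penalties: matrices with at most `k` nonzero rows (shared support, "HomL0"),
at most `k` nonzeros per column (class-specific supports, "HetL0"), at most
`k` nonzeros overall, or the convex l1-ball analogues of each. Rather than
optimizing over the set directly, the solver penalizes the squared Euclidean
distance to it:

    f_rho(B) = f(B) + (rho/2) * dist(B, S)^2.

The intercept row is exempt: projections pass it through unchanged, so it
never contributes to the distance. Because each constraint set admits a cheap
exact projection (a partial sort of row norms, per-column order statistics, or
the sort-based l1-ball projection), `dist` and its majorization are
inexpensive.

## The MM solver

Both the loss and the distance term are majorized at the current iterate
(anchor) `B_m`. The loss majorization replaces each label by a *shifted
response*: samples inside their epsilon-ball are pulled to their own
prediction (zero loss, zero force), samples outside are pulled to a convex
combination `w y_i + (1 - w) t(B_m) x_i` with `w = (||r|| - eps)/||r||`. The
distance term is majorized by `||B - P_S(B_m)||^2`. The resulting surrogate is
an ordinary penalized least-squares problem whose exact minimizer is

    B = (n^-1 X'X + rho I)^-1 (n^-1 X'Z + rho P).

With the thin SVD of the design cached once, the Woodbury identity reduces
every such solve — across all `(k, rho, epsilon)` settings — to re-inverting a
diagonal matrix, so one factorization serves an entire cross-validation run.
An SVD-free alternative takes a single steepest-descent step with the exact
line minimizer `gamma = ||G||^2 / (n^-1 ||XG||^2 + rho ||G||^2)`; both update
rules drive the penalized objective monotonically downhill (the MM descent
chain), and the tests verify they reach the same stationary point on strongly
convex instances.

The outer loop anneals `rho_t = min(rho_max, rho0 * mult^t)` with warm starts.
Inner loops stop on the gradient condition `||grad f_rho(B)|| <= delta_g`
(computable through MM tangency without differentiating the distance), and the
outer loop declares convergence as soon as the gradient condition holds
together with either `q_t <= delta_d` or `|q_t - q_{t-1}| <= delta_q`, where
`q_t` is the distance to the constraint set — even before `rho` reaches its
cap. The final iterate is projected onto the constraint set, so the returned
coefficients are exactly feasible.

### Defaults, and why

* `epsilon = 0.5` when not tuned: below `sqrt(2)/2 ≈ 0.707`, half the
  inter-vertex distance, so the loss-free balls of different classes cannot
  overlap. The tuning pipeline searches a log-spaced grid in `[0.05, 0.70]`.
* `rho0 = 0.01`, `mult = 1.5`, `rho_max = 1e6`. The small starting penalty is
  a deliberate choice: on the `1/(2n)`-normalized risk, a unit starting
  penalty already dominates the loss gradient and freezes the support of the
  very first ridge-like solve. With `rho0 = 0.01` the early path is
  loss-driven and support selection happens gradually; on an easy
  `n = 200, p = 100` recovery problem this is the difference between a
  true-positive rate of 0.4 and 1.0.
* `delta_g = 1e-4 * sqrt(q c)` (scale-aware in the coefficient count),
  `delta_d = 1e-3`, `delta_q = 1e-6`, at most 500 inner iterations.
* Nesterov acceleration uses the standard `(m - 1)/(m + 2)` weights with a
  restart on any objective increase, which preserves the descent guarantee.
* Standardization (z-scores from the training split only) is on by default;
  the loss and `epsilon` are scale-sensitive, and all simulation designs here
  have unit-variance columns so standardization is harmless there.
* `polish = TRUE` refits the selected coordinates by unpenalized
  epsilon-insensitive least squares after the final projection. Projection
  alone truncates a *penalized* solution and therefore biases coefficient
  magnitudes toward zero; the polish removes that bias without touching the
  support. It is off by default (the plain projected solution is the reference
  behavior) and on in the reproduction protocol below.
* Ties are broken deterministically everywhere a projection or a grid search
  can tie: lowest row/column index wins a projection tie, the smaller
  `epsilon` then the smaller `gamma` wins the tuning tie, and the smallest
  model size wins an accuracy tie (parsimony).

### Kernel VDA

With a reproducing kernel the design becomes the `n x n` Gram matrix
`W(x_i, x_j) = exp(-gamma ||x_i - x_j||^2)` (inputs standardized first, the
kernel matrix itself left as is) bordered by an intercept column. Each
coefficient row now belongs to a training instance, so row sparsity selects at
most `k` *avatars* — the analogue of support vectors — and column sparsity
selects avatars per class. The model stays linear in its parameters, so every
solver guarantee carries over unchanged. Prediction touches only avatar rows.
When `gamma` is not supplied it defaults to the median heuristic (the inverse
median pairwise squared distance). The `c`-dimensional encoding is used for
kernel models too, for the same class-specific-selection reason (a
`c - 1`-dimensional variant exists in older treatments; we standardize on
`c`).

## Hyperparameter tuning

`nested_cv()` implements a nested protocol: a stratified test split is held
out first (simulated benchmarks instead supply an independent test set); the
training portion is K-folded (3 folds below 200 samples, 5 otherwise);
`(epsilon, gamma)` are tuned by fold accuracy of the *dense* model (`gamma`
fixed at 0 for linear fits); then the model size `k` is tuned on the *same
folds*, scanning a log-spaced grid that covers about half the feature space,
from the largest size downward with warm starts along the path. The final
refit follows the same warm-started path down to the chosen size. Fold scores
are averaged (not pooled), and fold fits during the size search are scored
without the polish refit — polishing flatters oversized models and distorts
the size selection. `repeated_cv()` re-runs the pipeline under distinct seeds
and reports per-feature (and per-class) selection frequencies, 10/50/90%
quantiles (linear interpolation between order statistics) of the selected
size and test error, and signed coefficient summaries.

## The simulation design

`simulate_classification()` generates the support-recovery benchmarks:

1. `n` rows of `N(0, Sigma)` with Toeplitz covariance
   `Sigma_ij = corr^|i-j|`, drawn by the exact AR(1) recursion (an `O(np)`
   factorization of `Sigma`).
2. A ground-truth slope matrix `B*` with exactly `k*` informative rows:
   homogeneous — `k*` rows shared by all classes with entries uniform on
   `{-1, 1}` (every informative feature active in every class; an entry
   distribution over `{-1, 0, 1}` is the natural alternative and behaves
   equivalently in our checks); heterogeneous — `k*/c` disjoint rows per
   class. The informative submatrix is redrawn until it has full column rank.
3. Labels by the nearest-vertex rule applied to `t(B*) x`.
4. Noise `E` with variance `sigma^2 = mean_j Var(Y_j) / SNR`.
5. A sparse shift matrix, supported on the informative columns, solving
   `S_J B*_J = Y - X B* - E` (minimum-Frobenius-norm solution), after which
   `(X + S) B* + E = Y` holds exactly — the generator's defining identity,
   tested to `1e-9`.
6. An independent test set of 1000 samples produced by the same mechanism
   with fresh randomness. (A "shared shift" variant is not possible: the
   training shift has one row per training sample.)

What the generator emulates: high-dimensional designs with serially
correlated predictors, a small informative subset, class labels geometrically
tied to simplex vertices, and an SNR dial that moves test error from chance
to zero. What it does not emulate: heavy tails, outliers, batch effects,
heteroscedastic noise, or discrete genotype-like features — passing these
benchmarks says nothing about robustness to any of those.

The 2-D toys for kernel VDA are reconstructions (their original
parameterizations are not published): `circles` draws two concentric rings
(radii 1 and 2, radial noise 0.1) and flips each label with probability 0.20,
making the irreducible error exactly 20% by construction; `clouds` places `c`
unit-variance Gaussian blobs on a circle of radius 3; `spirals` uses
Archimedean arms with coordinate noise.

## Reproduction protocol and problem sizes

`scripts/acceptance.R` re-runs five simulation cells from scratch
(`p = 1000`, `k* = 30` throughout): the homogeneous row-sparse pipeline at
`(n = 500, c = 3)` for Toeplitz 0.1/SNR 0.1 and Toeplitz 0.9/SNR 10, at
`(n = 2000, c = 3, Toeplitz 0.1)` for SNR 10 and SNR 1, and the heterogeneous
column-sparse pipeline at `(n = 500, c = 10, Toeplitz 0.9, SNR 10)`. Each cell
reports the median test error on 1000 fresh samples over 10 replicates
(5 at `n = 2000`), using 3 tuning folds, an epsilon grid of `{0.3, 0.5}`, the
log-spaced size grid over half the feature space, and a polished final refit.
These sizes are the package's desk-scale protocol; they keep a full
reproduction under ten minutes on one core while leaving the medians stable.

## Known limitations

* The distance-penalized objective is nonconvex; the annealed MM path
  converges to a stationary point, not a certified global optimum. In the
  underdetermined, highly correlated homogeneous regime
  (`n = 500, p = 1000, c = 3`, Toeplitz 0.9, high SNR) the path frequently
  terminates at a sparse solution whose training risk is an order of
  magnitude above the planted optimum; warm-started size paths and the polish
  refit mitigate but do not eliminate this, and published error rates near
  zero in that one regime are not matched by this implementation. Convex and
  greedy baselines (lasso, hard thresholding, forward selection) fail on the
  same instances, so the gap is a search problem rather than a data problem.
* Selection among strongly correlated features is inherently unstable: often
  one representative of a correlated cluster is selected. `repeated_cv()`
  exists to make that instability visible rather than to remove it.
* The direct update factors the design once; for problems where even a thin
  SVD is out of reach, the steepest-descent path avoids it at the cost of
  more iterations.
* Convergence of the annealed path is checked empirically (descent,
  feasibility, stationarity diagnostics) rather than proved here.
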