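---
title: "Support matrix machines with model-parameter transfer: models, solvers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Support matrix machines with model-parameter transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klsmm)
```

## The problem

Motor-imagery brain-computer interfaces classify short EEG epochs into
imagined-movement classes. After band-power feature extraction, each trial is
naturally a matrix: rows indexed by spatial filters, columns by time
segments. Classifiers that vectorize these matrices discard the row/column
structure; a support matrix machine (SMM) keeps it by learning a matrix-valued
regression coefficient. The second difficulty is calibration cost: a new
subject supplies only a handful of labeled trials, and raw trials from other
subjects may be unavailable for privacy reasons. The knowledge-leverage SMM
(KL-SMM) addresses both at once: it is a matrix classifier whose fit is pulled
toward a *source subject's fitted coefficient matrix* — model-parameter
transfer that never touches the source subject's raw data.

## Model

For trials $X_i \in \mathbb{R}^{p\times q}$ with labels $y_i \in \{-1,+1\}$,
the decision function is $f(X) = \mathrm{tr}(W^\top X) + b$. `smm()` minimizes

$$
\tfrac12\,\mathrm{tr}(W^\top W) \;+\; \tau \lVert W\rVert_*
\;+\; C\sum_{i=1}^{N} \max\{0,\, 1 - y_i f(X_i)\}
\;+\; \lambda\, \mathrm{tr}\!\left[(W_s - W)^\top (W_s - W)\right].
$$

The first two terms are the spectral elastic net: the squared Frobenius norm
gives a grouping effect, the nuclear norm $\lVert W\rVert_*$ (sum of singular
values) is the convex surrogate of rank and biases $W$ toward low rank — the
structural prior that matrix-form EEG features justify. The hinge term is the
usual soft margin. The last term is the knowledge-leverage penalty: with
$\lambda > 0$ it shrinks the target coefficient matrix toward the source
matrix $W_s$. Setting $\lambda = 0$ recovers the plain SMM; setting, in
addition, $\tau = 0$ makes the model exactly a linear SVM on vectorized
trials (the Frobenius inner product is the dot product of the flattened
matrices) — both reductions are verified numerically in the test suite.

## Optimization

The objective splits into a smooth-plus-hinge part in $(W, b)$ and the
nuclear-norm part, linked by an auxiliary $S = W$ with multiplier $\Lambda$
and penalty $\rho$ (ADMM). Each iteration solves:

1. **$(W, b)$ subproblem** through its dual, a box-constrained QP with a
   single equality constraint:
   $\max_\alpha -\tfrac12 \alpha^\top K \alpha + H^\top\alpha$ over
   $0 \le \alpha \le C$, $\alpha^\top y = 0$, with
   $K_{ij} = y_i y_j\,\mathrm{tr}(X_i^\top X_j)/(2\lambda+\rho+1)$ and
   $h_i = 1 - y_i\,\mathrm{tr}[(\Lambda + \rho S + 2\lambda W_s)^\top X_i]/(2\lambda+\rho+1)$.
   Then $W = (\Lambda + \rho S + 2\lambda W_s + \sum_i \alpha_i y_i X_i)/(2\lambda+\rho+1)$,
   and $b$ is averaged over the on-margin support set.
2. **$S$ subproblem** in closed form by singular value thresholding:
   $S = \mathcal{D}_\tau[\rho W - \Lambda]/\rho$. The $1/\rho$ factor is
   required by the optimality condition of the subproblem
   ($0 \in \Lambda - \rho W + \rho S + \tau\,\partial\lVert S\rVert_*$);
   the package verifies this numerically through the subgradient-distance
   residual at every `admm_update_S()` output tested.
3. **Multiplier update** $\Lambda \leftarrow \Lambda + \rho\,(S - W)$.

Convergence is declared when the primal residual $\lVert S - W\rVert_F$ falls
below `tol_primal` $\times \max(1, \lVert W\rVert_F)$ *and* the relative
objective change falls below `tol_obj`. At termination the fit carries
certificates: the stationarity residual of the $W$ update (zero up to
floating-point by construction), the dual KKT residual, and the full
objective/primal traces.

### The dual QP solver

The solver is sequential minimal optimization: pairwise coordinate ascent
along directions $y_i e_i - y_j e_j$ (which preserve the equality constraint
exactly), with the maximal violating index paired against a second-order
(maximal-gain) partner, and exact line search clipped to the box. Pairwise
ascent stalls when many support vectors are free and the reduced Hessian is
ill-conditioned — exactly what happens with rank-deficient Gram matrices of
vectorized trials (200 trials in a 30-dimensional feature space). The solver
therefore interleaves, every 50 updates, an exact ascent on the current free
set: a reduced Newton step computed in the null space of the equality
constraint by eigendecomposition, plus a box-capped move along numerically
flat eigendirections that still carry gradient. Every move is an exact line
search on a concave quadratic, so the dual objective never decreases and
feasibility is maintained exactly. The Gram matrix receives a `1e-10` ridge
only if its smallest eigenvalue estimate is negative. `alpha` is warm-started
across ADMM iterations.

### Accelerated mode

The fitting function also offers a restarted accelerated ADMM
(`accelerated = TRUE`): Nesterov-type extrapolation of $(S, \Lambda)$ with
weight sequence $v^{(1)} = 1$,
$v^{(l+1)} = (1+\sqrt{1+4v^{(l)2}})/2$, and a restart triggered when the
combined residual fails to decay by the factor `eta` (default 0.999). Both
modes reach the same objective to within $10^{-5}$ on the test problems. The
plain solver's objective trace decreases monotonically (asserted with
$10^{-10}$ relative slack after a 5-iteration burn-in); the accelerated trace
can tick up by order $10^{-6}$ relative around a restart, because the restart
rule monitors the combined residual rather than the primal objective, so its
monotonicity is asserted with $10^{-4}$ relative slack.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `C` | hinge-loss weight | 1 | CV grid `10^(-6:1)` (8 values) |
| `tau` | nuclear-norm weight | 0.1 | CV grid: 1–2–5 ladder, `1e-5`–`1e0` (16 values) |
| `lambda` | transfer weight | 0 | CV grid: 1–5 ladder, `1e-4`–`1e0` (9 values) |
| `rho` | ADMM penalty | 1 | fixed across iterations; keeps the dual well-scaled |
| `tol_primal` | primal residual tolerance | `1e-4` | relative to $\max(1,\lVert W\rVert_F)$ |
| `tol_obj` | objective-change tolerance | `1e-6` | relative |
| `max_iter` | ADMM iteration cap | 500 | |
| `eta` | restart decay factor | 0.999 | accelerated mode only |

The CV grids are the selection sets used throughout the evaluation helpers
(`default_grids()`); selection is stratified k-fold CV maximizing mean
accuracy, with folds capped at the smallest class count (down to leave-one-out
within a class for 8-trial calibration sets) and ties broken toward the
smallest `C`, then `tau`, then `lambda` — the simplest model. No value of
`rho` is prescribed by the underlying theory; 1 is a conventional fixed
choice, exposed for the user.

Other conventions: a decision value of exactly zero predicts the positive
class; arbitrary two-valued label codings are accepted and mapped internally
to $\pm 1$ in first-seen order, recorded in the model; `W`, `S`, `Lambda`,
and `b` start at zero, and the optimizer uses no randomness, so fits are
deterministic.

## The EEG feature front-end

`bandpass_epochs()` applies a fifth-order Butterworth band-pass (8–30 Hz by
default, the mu/beta range of motor imagery) forward and backward
(zero-phase). The zero-phase choice is standard for offline pipelines — it
avoids latency distortion of the 0.5–3 s post-cue analysis window — and
squares the magnitude response relative to a single pass; the tests compare
measured tone gains against the analytic response of the design.
`fit_spatial_filters()` learns CSP filters from trace-normalized,
identity-shrunk (coefficient $10^{-6}$) class covariances via whitening plus
a symmetric eigenproblem, taking the most discriminative filters from both
ends of the eigenvalue spectrum. `band_power_matrix()` projects trials onto
the filters, splits the window into equal segments, and takes per-filter,
per-segment log variance (floored at $\log 10^{-12}$ for degenerate constant
segments). The resulting `n_filters x n_windows` matrix (default 6 x 5; both
configurable) feeds the matrix classifiers; rows carry spatial structure,
columns temporal structure. The exact matrix layout of band-power features is
a package choice — no canonical layout exists — and per-entry z-scoring with
training-set statistics is provided as a separate, default-recommended step
(`fit_feature_scaler()`/`apply_feature_scaler()`).

## Synthetic study conditions

The generators make every stage testable without external downloads. They are
pure functions of their seeds.

* `make_lowrank_model()` draws a unit-Frobenius rank-`r` source matrix
  $W_s = AB^\top$ and a target $W_t = \mathrm{normalize}(W_s + \text{shift}\cdot E)$;
  `shift` emulates cross-subject variation (at `shift = 0` the two are
  identical by construction).
* `sample_matrix_dataset()` draws standard-normal trial matrices, labels them
  by the sign of the true decision value, rejects trials with decision
  magnitude below $0.1\cdot\lVert W\rVert_F$ (so that 8-trial calibration
  sets remain learnable), and flips labels independently with probability
  `label_noise`.
* `make_transfer_task()` mirrors the cross-subject protocol: a 200-trial
  source set (label noise 0.05) fits the source SMM; the target supplies
  train/test splits with the first `n_labeled` trials (8, 14, or 20 in the
  evaluation helpers) as calibration data, presented in alternating class
  order as balanced cue sequences are in practice — this also guarantees the
  calibration prefix contains both classes.
* `synth_eeg()` plants an ERD-like effect: band-limited noise sources mixed
  into channels by a random matrix, with the first source's variance
  attenuated by `effect_size` in one class. At `effect_size = 1` the classes
  are identical and decoding sits at chance; at 0.3 with three channels the
  CSP + band-power + SMM pipeline separates the classes essentially
  perfectly at 100 training trials.

What these generators do *not* emulate: real EEG nonstationarity within a
session, artifacts, volume-conduction structure beyond a single static mixing
matrix, class-conditional covariance differences richer than one attenuated
source, and realistic cross-subject feature-distribution shifts. Passing
tests on them certifies the optimization machinery, the reductions between
models, and the qualitative transfer behavior — not clinical-grade decoding
performance.

## Behavior under transfer, and how the checks are sized

With a well-aligned source (small shift), test accuracy at 8 labeled trials
rises markedly with $\lambda$: the source model substitutes for the missing
calibration data. The package's evaluation asserts this as a paired
comparison over 50 seeded tasks between the CV-tuned KL-SMM and the plain
SMM (sign test at the 5% level; the mean gain is about 13 accuracy points
under the default conditions). $\lVert W_t - W_s\rVert_F$ is non-increasing
in $\lambda$ on essentially every task, and $\lambda = 10^8$ reproduces
$W_s$ to relative error below $10^{-3}$.

The rise-then-fall sensitivity profile needs conditions where the pure-source
asymptote is visibly worse than the best blend. Within the 9-point selection
grid (up to $\lambda = 1$) the asymptote is not yet reached at any shift, so
the sensitivity check sweeps an extended grid (up to $\lambda = 100$) at
`shift = 2` (source-target cosine $\approx 0.45$): the 30-seed mean profile
rises by roughly 4–6 accuracy points to an interior maximum and falls by
3–4 points toward the pure-source level. With an *uninformative* (orthogonal)
source the effect of large $\lambda$ is negative on average (about −3
points at $\lambda = 1$), though not in every seed: at 8 trials the transfer
term also acts as a ridge on the data term, which can help by chance.
Per-seed accuracy monotonicity claims are asserted endpoint-wise because a
100-trial test set quantizes accuracy in steps of 0.01.

## Numerical choices and degenerate inputs

* Numerical rank in `condensed_svd()` uses a relative cutoff `rank_tol`
  (default $10^{-12}$ of $\sigma_1$). Ties among singular values make the
  factors non-unique; all downstream quantities are basis-invariant, and
  tests compare reconstructions, never factors.
* The subgradient-distance residual combines in-subspace leakage and excess
  spectral norm via a maximum — one scalar usable as a test assertion.
* The on-margin support set for the intercept is
  $\{i : \varepsilon < \alpha_i < C - \varepsilon\}$,
  $\varepsilon = 10^{-8} C$; it falls back to $\{\alpha_i > \varepsilon\}$,
  then to all trials (with a warning) when empty — the margin identity
  $y_i = f(X_i)$ only holds for on-margin vectors, so the chain prefers them.
* Single-class training data is an error everywhere; the synthetic samplers
  re-draw to guarantee two trials per class.
* Constant EEG segments would give $\log 0$; the variance floor prevents it.
* Serialization uses a JSON archive with full-precision numbers; arrays
  round-trip to better than $10^{-15}$ relative error and metadata exactly.

## Problem sizes used by the checks

The bundled test-suite and the acceptance script run entirely on synthetic
data at desk scale: 200 random matrices for prox-optimality, 20 datasets of
30 trials for the SVM-equivalence chain, 50 random small QPs against a
feasible-point search, 12 ADMM configurations, 50 seeded 8-trial transfer
tasks for the benefit comparison, 30 for the sensitivity profile, and one
200-trial synthetic EEG study. These sizes give stable averages for every
asserted quantity while each stage remains quick to re-run.

## Known limitations

* Binary classification only; multiclass and sparse variants are out of
  scope, as are kernelized and online fits.
* One source model; multi-source weighting is not implemented (the adaptive
  SVM baseline accepts any externally supplied decision function).
* The adaptive SVM baseline adopts the classical perturbation form
  $f(x) = \lambda_A f_s(x) + w^\top x + b$ with hinge loss on the combined
  decision — where exactly the scaling enters is a documented package choice.
* The bilinear (factorized) matrix SVM is not reimplemented; it is a
  different, non-convex method and enters only as a potential external
  comparator.
* GDF ingestion is not bundled; any epoched `trials x channels x samples`
  array with a sampling rate satisfies the `epoch_array()` contract, so an
  external reader can be adapted in one line.
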