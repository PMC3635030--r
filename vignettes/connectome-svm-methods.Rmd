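---
title: "Methods: connectome construction, SVM analysis, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome construction, SVM analysis, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connsvm)
```

This vignette records the modelling choices behind `connsvm`: the exact
conventions the pipeline fixes, the solvers and their numerical
behaviour, what the synthetic cohort generator does and does not
emulate, and the design decisions that were genuinely open.

## 1. The connectome and its feature-index convention

A scan's connectome is the strict lower triangle of the ROI-by-ROI
Pearson correlation matrix after Fisher's variance-stabilizing
transform `z = atanh(r)`. For `N` ROIs that is `N(N−1)/2` values; with
the standard 100-ROI set, 4950. The enumeration is **column-major,
1-based**:

$$k(i, j) = (j - 1)N - \tfrac{j(j-1)}{2} + (i - j), \qquad i > j,$$

which is identical to R's `lower.tri()` ordering. This convention is
not arbitrary: published consensus-feature tables for this ROI set
print both feature numbers and ROI pairs, and three independent rows
(pairs (60, 7) → 632, (15, 12) → 1037, (88, 83) → 4802) ratify exactly
this enumeration; any row-major, diagonal-including, or 0-based variant
contradicts them. `pair_to_feature()` / `feature_to_pair()` implement
the bijection and the test suite checks it exhaustively over all 4950
indices.

Correlations are clipped to `|r| ≤ 1 − 10⁻⁷` before `atanh` so that
degenerate synthetic inputs (identical series, `r = ±1`) stay finite.

## 2. Temporal preprocessing

Two steps of the published pipelines are in scope here, applied to the
extracted ROI series (everything voxel-wise — motion correction,
smoothing, registration, nuisance regression — is assumed done
upstream and is out of scope):

- **Detrending** removes the least-squares fit of `{1, t, t²}` per ROI
  (a QR projection, hence idempotent and exactly orthogonal to the
  basis).
- **Band-pass** keeps DFT components with `0.005 ≤ f ≤ 0.1` Hz,
  inclusive edges, as an ideal frequency-domain mask; DC is always
  removed, so filtered series are mean-zero. At TR = 2 s and 128
  volumes the resolvable grid is multiples of 1/256 Hz, so the band
  retains bins 2–25.

The order — detrend, then filter — is a package choice: the reference
description lists the two operations in one sentence without fixing an
order, and removing polynomial trends first keeps spectral leakage of
a strong quadratic drift out of the pass band. For in-band sinusoids
the two orders agree to numerical precision.

Sphere extraction uses voxel-center-within-radius membership (Euclidean
distance in world mm), the simplest defensible discretization given
that ROIs are specified only by centre and radius. All public
coordinates are in mm; voxel indexing never leaks into the interface.

## 3. Solvers

### Binary SVM and SVR

The binary soft-margin dual and the ε-insensitive SVR dual are solved
by an SMO-style method: precompute the kernel matrix, repeatedly pick
the maximal violating pair of coordinates, and solve the two-variable
subproblem analytically. For SVR the dual is optimized in the
collapsed variables `β_i = α_i − α*_i` (box `[−C, C]`, one equality
constraint); the ε‖β‖₁ term makes the one-dimensional line search
piecewise quadratic with kinks where a `β` crosses zero, which is
solved exactly per segment. Convergence is declared at a KKT violation
below `10⁻⁸ · max(1, C)`; coefficients within `10⁻¹⁰C` of a bound are
snapped to it, which matters for degenerate pair selection (a
coefficient numerically *at* a bound must not be proposed as movable).

The bias `b` is the mean over margin support vectors (`0 < α < C`); if
none exist, the midpoint of the KKT-feasible interval. Linear models
also carry the explicit weight vector `w = Σ y_i α_i x_i` (SVM) or
`Σ β_i x_i` (SVR). RBF models (σ = 2 by default) deliberately have no
`w`: kernel-space weights are not per-feature contributions, and the
interpretation functions refuse them rather than approximate.

### Weston–Watkins multiclass

The multiclass model solves the all-at-once joint problem (margin
constant 1, which only rescales the solution relative to other margin
conventions and leaves predictions unchanged):

$$\min \tfrac12 \sum_m \lVert w_m\rVert^2 + C \sum_i \sum_{m \ne y_i} \xi_{im}
\quad \text{s.t.} \quad (w_{y_i}-w_m)\cdot x_i + b_{y_i}-b_m \ge 1 - \xi_{im},\; \xi_{im}\ge 0.$$

It is assembled as an explicit primal QP. The generic QP engine
(`pracma::quadprog`) terminates around 10⁻⁵ relative accuracy, which
is too loose to verify optimality identities, so its solution is
polished by an active-set refinement (KKT solve on the working set,
most-violated-constraint insertion, negative-multiplier deletion) down
to ~10⁻¹⁰. A ridge of 10⁻¹⁰ regularizes the bias/slack block, which
enters the objective only linearly; its effect on the reported
objective is below 10⁻⁷ at the problem sizes used.

### Verification by duality

Every solver is checked against an independently derived *dual* (or
for the multiclass primal, its Lagrangian dual in the variables
`α_{im}`), solved in the test suite by a separate textbook active-set
QP. Strong duality makes agreement of the two optimal values a
meaningful two-route check; the suite requires 10⁻⁶ relative agreement
over ≥ 50 random instances and typically observes 10⁻⁸–10⁻¹².
`e1071` (libsvm) and `kernlab` serve as additional independent
prediction cross-checks, never as the implementation.

## 4. Cross-validation and inference

The unit of cross-validation is the **subject**: each fold removes all
scans of one subject, because within-subject scans are far more alike
than between-subject scans and splitting them across train and test
("twinning") inflates accuracy. The guard is structural — the fold
constructor cannot emit a training row sharing the held-out subject —
and mutation tests confirm that rewriting a held-out subject's scans
never changes that fold's selection or model.

Choices the reference design leaves open, fixed here and documented
prominently because they affect reported accuracy:

- **Scan-to-subject aggregation.** Classification: majority vote over
  the subject's scans, ties broken by the sign of the summed decision
  values. Regression: the mean of scan predictions (the minimum-
  variance unweighted choice).
- **Filter granularity.** The t/correlation filter runs on training
  *scans* (n = 3 × subjects), not subject averages.
- **Accuracy denominator.** Subjects, consistent with treating each
  fold as a Bernoulli trial.

Significance is the exact binomial upper tail
`Pr(X ≥ n_correct)` at chance 1/2 (binary) or 1/K (multiclass) — never
a normal approximation; at n ≤ 100 the exact sum is cheap.

One caution established empirically by the test suite: under the
*null* (labels permuted), subject-grouped LOOCV accuracy is not
binomially distributed. Leaving out one subject makes its class the
training minority, and with little real signal the classifier drifts
toward the majority class — an anti-learning bias that over-disperses
and slightly depresses null accuracy. Single-permutation accuracies
therefore escape the exact binomial 99% band in roughly a third of
draws at 60 subjects, while the mean over 20 permutations sits
comfortably inside it; the acceptance checks use that mean, and the
unit tests assert the operationally important property that permuted
labels never reach significance.

### Tuning

Grid search maximizes holdout LOOCV accuracy over `k × C`
(classification) or slope-then-R² over `k × ε` (SVR), with
deterministic tie-breaks (smaller `k`, then smaller `C`; larger R²,
then smaller `k`) so reruns are identical. Mirroring the original
design, the tuned parameters are then applied to the full dataset
*including* the holdout; the induced optimism is documented in the
README. Defaults mirror the published tuned values: `k = 100, C = 0.1`
(binary linear), `k = 62, C = 1` (RBF), `k = 28, C = 0.1` (multiclass),
`k = 298, ε = 0.1` (SVR). The SVR's `C` is not printed anywhere in the
reference material; the package defaults to `C = 1` and exposes it.

## 5. Interpretation

Consensus features are the intersection of per-fold selections — the
connections the filter found informative no matter which subject was
held out. Their reported weight is the **mean over folds** of the
linear model's coefficient (the reference tables print a single weight
per feature without stating the aggregation; the mean is seed-stable
and unbiased across folds), with the magnitude alongside so
cancellation across folds is visible rather than hidden.

A node's weight is `|Σ incident signed weights| / 2`. The ½ constant
is ratified by printed tables: for every ROI whose incident printed
feature weights share a sign (e.g. ROIs 7, 12, 15, 60 of the binary
classifier's tables; ROI 12 of the SVR's), half the sum reproduces the
printed node weight to its full 4-digit precision — the bundled
example tables under `inst/extdata/` carry exactly this check in the
test suite. For high-degree nodes the printed feature *magnitudes*
cannot reproduce the printed node weight, consistent with some signed
weights being negative before magnitudes were taken; the per-edge
signs are unrecoverable from printed data and are not guessed.

BrainNet Viewer export writes the standard whitespace-delimited
`.node` file (x, y, z, color, size = node weight, label) and the full
symmetric `.edge` matrix of feature magnitudes.

## 6. The synthetic cohort model

`generate_cohort()` draws, for each scan of subject `s` with age `a`,

$$z_{e} = z_0 + \beta_e \frac{a - 50}{10} + u_{s,e} + \varepsilon_{e},$$

with planted slopes `β_e = ±edge_effect` (alternating sign — aging
both strengthens and weakens connections) on a seeded random subset of
edges and `β_e = 0` elsewhere; `u_{s,e} ~ N(0, subject_sd)` is shared
across the subject's scans and `ε ~ N(0, scan_sd)` is fresh per scan.
Defaults: `baseline_z = 0.3` (a typical within-network resting
correlation of r ≈ 0.29), `subject_sd = scan_sd = 0.1` z-units — the
1:1 ratio is a declared free knob, since within-subject between-scan
dependence has no reference value — and ages uniform within each
group's range (the least-assumption distribution matching a printed
range). Sex alternates within group and carries no effect, matching
the null gender result the analysis design anticipates. Centring the
age effect at 50 keeps the truth interpretable and matches the linear
predictability the SVR assumes.

All randomness flows from one integer seed; group-level draws, the
edge subset, per-subject noise, and per-scan rendering each use a
derived sub-stream, so enlarging the last group leaves every existing
subject's data bit-identical.

`render_timeseries()` realizes a target z-matrix as Gaussian series:
`tanh` back to correlations, projection to the nearest valid
correlation matrix (Higham's algorithm via `Matrix::nearPD` — planted
z-matrices need not be positive definite), Cholesky factorization, and
sampling, so the sample correlation converges to the projected target
at the Fisher rate `SE(z) ≈ 1/√(n_volumes − 3)`. `render_volumes()`
paints series into atlas spheres on a voxel grid with a proper
voxel-to-mm affine, giving an end-to-end NIfTI fixture.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: hemodynamics, motion and scanner
drift (beyond white noise), spatial autocorrelation between
neighbouring ROIs, heavy-tailed or non-Gaussian connectivity
distributions, site or acquisition differences between scans (the
reference acquisition varies voxel size across a subject's three
scans; the generator does not), and any nonlinear age effect. Results
on synthetic cohorts demonstrate that the pipeline recovers the
effects it assumes, at the sizes it assumes — not that those
assumptions hold in vivo.

## 7. Acceptance-scale simulation settings

The heavier checks run at the cohort sizes the analysis design names,
chosen once and fixed:

- **Classification recovery:** 30 + 30 subjects (ages 19–35 / 55–85),
  3 scans, 100 ROIs, 50 informative edges at a scan-level Cohen's
  d ≈ 1.5 (`edge_effect_for_d()` converts d to a slope given the noise
  sds: β ≈ 0.049 z/decade). Thresholds: subject accuracy ≥ 0.90 and
  ≥ 60% of planted edges selected in every fold — artifact-defined
  recovery targets, not empirical claims.
- **SVR recovery:** 65 subjects (28 aged 19–37, 22 aged 42–60, 15 aged
  61–85), 50 informative edges at 0.05 z/decade; thresholds R² ≥ 0.5,
  slope in [0.4, 1.0]; age-permuted control R² < 0.1.
- **Solver duality:** ≥ 50 random instances at n ≤ 30 (binary, SVR)
  and n ≤ 12, K = 3 (multiclass), 10⁻⁶ relative.

These sizes complete in a few minutes on one CPU while keeping all
statistical margins wide (the observed values are accuracy 1.0, recall
1.0, R² ≈ 0.93 — far from the thresholds).

## 8. Known limitations

- `qp_ineq()`'s active-set polish assumes the working set stays
  numerically well-conditioned; for the desk-scale multiclass problems
  used here that always holds, but the solver is not intended for
  thousands of examples.
- The ideal band-pass mask has sharp spectral edges (ringing in the
  time domain); it reproduces the AFNI-style filtering the reference
  pipeline used, not a causal filter.
- `welch_t` ranks features only; it deliberately computes no degrees
  of freedom and must not be used for p-values.
- Holdout-then-full-data tuning is mildly optimistic by construction
  (see README).
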