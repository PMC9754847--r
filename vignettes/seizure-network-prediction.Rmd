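---
title: "Dynamic functional connectivity for seizure prediction: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity for seizure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizconn)
```

## The problem and the model

Scalp EEG of a patient with epilepsy moves through four states — ictal
(the seizure), postictal (recovery), interictal (baseline) and preictal
(the window before the next seizure). If the preictal state can be
recognized, a warning can be raised before the seizure. `seizconn` frames
this as epoch classification: continuous EEG is cut into nonoverlapping
60-second epochs, each epoch is reduced to one average amplitude per
electrode per second, and the task is to label each p × q epoch matrix
X (p electrodes, q = 60 seconds) as preictal (Z = 1) or interictal
(Z = 0).

Each epoch is modeled as matrix-normal, X ~ MN(M, Σ_T ⊗ Σ_S): the
temporal covariance Σ_T captures within-epoch autocorrelation, and the
spatial precision matrix Ω_S = Σ_S⁻¹ encodes conditional dependence
between electrodes — the functional connectivity network. The working
hypothesis, supported by the epilepsy literature, is that preictal and
interictal states differ in Ω_S.

### Stage 1: kernel-weighted time-varying precision estimation

Brain networks are not static even within a minute of EEG, so the spatial
covariance at time t is estimated with all q columns, down-weighted by
temporal distance through a Gaussian kernel K(u) = exp(−u²/2):

Σ̂(t) = Σᵢ w_it X·ᵢ X·ᵢᵀ / Σᵢ w_it,  w_it = K(|i − t| / h).

The q per-time estimates are then averaged, S̄ = (1/q) Σₜ Σ̂(t), giving
one epoch-level covariance that was nonetheless built from a time-varying
estimator. A single sparse precision matrix per epoch is obtained from
the graphical lasso, minimizing Tr(S̄Ω) − log det Ω + λ‖Ω‖₁ (off-diagonal
penalty by default), and converted to partial correlations
W_ij = −ω̂_ij/√(ω̂_ii ω̂_jj). The row-major upper triangle of W — d =
p(p−1)/2 edge strengths — is the epoch's feature vector; epochs stack
into the n × d network predictor matrix V (alternative feature modes
`raw`, the flattened p·q amplitudes, and `combined` exist for
comparison).

Implementation note: because each Σ̂(t) is the same outer-product sum
under different column weights, the average collapses exactly to a single
weighted covariance with weights a_i = (1/q) Σ_t w_it / Σ_j w_jt;
`averaged_covariance()` computes that collapsed form and the tests verify
it against the literal double sum to 1e−12.

### Stage 2: bootstrap-ensembled lasso logistic regression

With d up to a few hundred edges and often ~100 epochs, a single logistic
fit is unstable. The package fits lasso-penalized logistic regression on
B class-stratified bootstrap resamples (n₁ preictal and n₂ interictal
draws, with replacement). The ensemble probability of a new epoch is the
mean of the B per-model probabilities, and each edge receives

ψ_i = (1/B) Σ_b 1(β̂_i⁽ᵇ⁾ ≠ 0),

its selection frequency — a stability-selection-style importance weight
in {0, 1/B, …, 1}. Sensitivity, false discovery rate and AUC (Mann–Whitney
rank form, average ranks on ties) summarize performance; the reported
cutoff maximizes accuracy over the midpoints of adjacent sorted unique
probabilities plus {0, 1}, ties resolved toward the smallest cutoff.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `epoch_seconds` | 60 s | epoch length; q = 60 after per-second averaging |
| `preictal_minutes` | 30 min | preictal horizon before onset (the positive class) |
| `postictal_hours` | 2 h | postictal exclusion; also the minimum inter-seizure gap below which the later seizure is dropped |
| kernel bandwidth h | q^(1/3) | smoothing span of the time-varying covariance; `bandwidth_rule = "fixed"` overrides |
| `lam` (stage 1) | 0.1 | graphical-lasso penalty on the correlation-rescaled S̄; shared across a patient's epochs so edge scales are comparable |
| `center` | TRUE | subtract per-electrode within-epoch means before covariance (the matrix-normal mean M is unknown); `FALSE` reproduces the raw second-moment form |
| `scale_correlation` | TRUE | rescale S̄ to unit diagonal before the penalty, making one λ meaningful across channels with different amplitudes |
| `B` | 100 | bootstrap replicates; ψ resolution is 1/B |
| stage-2 penalty | CV once | chosen by stratified cross-validation on the full training split and reused for all B fits (per-bootstrap CV would be 10–50× slower for little gain) |
| `k` | 5 | stratified CV folds for evaluation |

Two readings of the bandwidth rule "h = n^(1/3)" are defensible — n as
the number of time points the kernel smooths over (q), or as the number
of epochs. The kernel runs over within-epoch time, so the package uses
q by default; a fixed-bandwidth override covers the other reading.
Similarly, the edge strength is taken to be the partial correlation
rather than the raw precision entry (the standardized quantity is
comparable across electrodes); raw precision values remain available via
`partial_correlation()`'s input.

## Evaluation protocol

The per-patient split protocol behind published seizure-prediction tables
is rarely stated fully; this package documents its own: stratified k-fold
cross-validation over epochs, ensemble refit per fold, probabilities
pooled out-of-fold, cutoff chosen on the pooled probabilities, ψ from a
final all-data refit. Stage-1 features are a per-epoch transform with a
fixed global λ — no statistic is pooled across epochs — so computing them
once for all epochs is exactly equivalent to recomputing them inside each
training fold; no information leaks from held-out epochs.

## What the simulator emulates — and what it does not

`simulate_epoch_set()` draws epochs from the model itself: a shared
Erdős–Rényi baseline precision support (`edge_prob`, entries ±`delta`),
`n_diff` extra preictal-only edges of magnitude `delta`, AR(1) temporal
covariance (ρ^|i−j|, default ρ = 0.3, a one-parameter stand-in for EEG
autocorrelation), and iid observation noise (default sd 0.1). Both
precision matrices receive the same diagonal — |min eigenvalue| + 1 over
the two off-diagonal patterns — so they are SPD and differ in *exactly*
the planted positions; a per-matrix diagonal would leak class information
through every partial correlation. Default study conditions are p = 10,
q = 60, n₁ = n₂ = 60, n_diff = 5, delta = 0.4: a desk-scale problem
(minutes, one CPU) with realistic effect size after the diagonal shift
(planted partial correlations ≈ 0.2).

What the simulator deliberately does not reproduce: EEG waveform
morphology (spikes, rhythms, artifacts), nonstationarity *within* an
epoch, volume conduction, montage-specific correlation structure, or
non-Gaussian tails. Passing tests therefore demonstrate that the
estimator and classifier recover the structures the model assumes — not
that real scalp EEG satisfies those assumptions. Real-data performance
must be established on real recordings via the EDF pathway.

## Numerical choices

* **Graphical lasso solver.** Blockwise coordinate descent on the dual
  (one lasso subproblem per column), warm-started across sweeps;
  convergence when the mean absolute off-diagonal change of the dual
  variable falls below `tol` (1e−5 default), `max_iter` 200 sweeps, with
  a convergence-failure condition carrying the last iterate. λ = 0
  returns the unpenalized inverse, ridged by `ridge_eps`·I if singular.
  Zero-variance channels have their variance floored at `ridge_eps` with
  a warning. Exact zeros come from the lasso subproblems, so the reported
  support is not threshold noise; KKT residuals at convergence are ~1e−7
  on p = 15 problems (tests assert ≤ 1e−4).
* **Support monotonicity caveat.** The off-diagonal support of the
  graphical lasso is *typically* but not provably monotone in λ: the test
  suite itself contains a reproducible random matrix whose exact solution
  (confirmed by an independent proximal-gradient solver) has 39 edges at
  λ = 0.02 and 41 at λ = 0.05. The corresponding acceptance test reports
  this honestly rather than excluding the matrix.
* **Ties and degeneracies.** Cutoff ties break toward the smallest
  candidate; ψ ranking ties break by ascending edge index; FDR is defined
  as 0 when nothing is called positive; AUC uses average ranks on tied
  probabilities and is NA (with a warning) for single-class inputs.
* **Determinism.** Every stochastic step (bootstrap draws, fold
  assignment, penalty CV, simulation) flows from one user seed through
  derived sub-seeds; RNG state is restored on exit, and identical
  seeds reproduce results bit-for-bit.
* **Epoching arithmetic.** Non-integer samples-per-second are rejected
  rather than resampled (averaging stays exact); partial trailing windows
  are discarded, never padded; preictal windows colliding with an earlier
  exclusion or the recording start are truncated (and flagged) rather
  than dropped, keeping every usable full epoch.

## Known limitations

* The preictal horizon is fixed (30 min) for all patients, though true
  horizons are heterogeneous.
* λ is global per patient; per-epoch penalty selection would break the
  comparability of edge scales that stage 2 relies on.
* The ensemble gives selection frequencies, not calibrated probabilities
  or hypothesis tests; ψ ranks candidate connectome markers but does not
  certify them.
* The EDF reader targets the common 16-bit EDF/EDF+ layout with a single
  sampling rate across data channels; mixed-rate layouts are rejected
  rather than resampled.
* Problem sizes in the test suite (p = 10, ≈ 120 epochs, B = 50, 10–20
  seeds) are the package's documented desk-scale study conditions; they
  exercise every code path at meaningful signal strength while keeping a
  full run in minutes.
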