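---
title: "Detecting pilot mental states from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pilot mental states from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegstate)
```

## The problem

Attention-related performance deficiencies in pilots — channelized attention
(CA, absorption in a single task), diverted attention (DA), and
startle/surprise (SS) — are a recognized aviation-safety concern. `eegstate`
implements an end-to-end pipeline that classifies these three states against
the normal (NE) baseline from multichannel EEG alone: automated artifact
repair, covariance-based Riemannian features, and a soft-voting ensemble of
tree classifiers, evaluated under stratified 5-fold cross-validation.

Real cockpit EEG archives are large and external; the package therefore
ships a seeded synthetic generator whose recordings carry *known* class
structure and *annotated* artifacts, so every stage — and the pipeline
end-to-end — is testable at desk scale with no downloads. Pointing the same
functions at real CSV recordings only requires `read_recording()` with the
appropriate column layout.

## The model

**Features.** A one-second EEG epoch `X` (channels x samples, microvolts) is
summarized by a spatial covariance matrix, a symmetric positive-definite
(SPD) object. SPD matrices live on a curved manifold; the natural
(affine-invariant) geometry has distance
`delta(P1, P2) = ||log(P1^{-1/2} P2 P1^{-1/2})||_F`, exponential map
`Exp_P(S) = P^{1/2} exp(P^{-1/2} S P^{-1/2}) P^{1/2}` and its inverse
logarithmic map. Classifiers that assume Euclidean geometry operate on the
tangent space at the Frechet mean `C` of the training covariances: each
matrix maps to `s_i = vec(log(C^{-1/2} P_i C^{-1/2}))`, a vector of length
`n(n+1)/2` whose norm equals the Riemannian distance from the mean. The
`vec` flattening scales off-diagonal entries by `sqrt(2)` so it is an
isometry. Note the whitened form of the logarithm: the printed exponential
and logarithmic maps are exposed verbatim as `exp_map()` / `log_map()`, but
vectorizing the *whitened* log is what makes Euclidean distances in the
feature space agree with manifold distances near the mean (the package
tests verify this local isometry to 5% for points within 0.3 of the base).

**xDawn augmentation.** Before the covariance is taken, each epoch is
augmented with class information: per class, spatial filters maximize the
Rayleigh quotient of the evoked prototype's variance against the total
signal variance (solved by Cholesky whitening and a symmetric
eigendecomposition), and the filtered class prototypes are stacked above the
filtered epoch. With K = 4 classes and `nfilter = 6` filters per class the
super-trial has 48 rows, its shrunk covariance is 48 x 48, and the tangent
vector has 48 * 49 / 2 = 1176 entries. `nfilter = 6` is the default
precisely because it reproduces those published feature dimensions.

**Dimension reduction.** The 1176 tangent coordinates are projected onto the
top `n_pca = 60` principal components; a Fisher geodesic discriminant
analysis (FGDA) — Fisher discriminant filtering in the tangent space,
projecting onto at most K - 1 discriminant directions and back — is fitted
*in the PCA score space*; finally a one-way ANOVA F score ranks the filtered
components and the top `k_anova = 40` are kept. Fitting FGDA after PCA
rather than before is a deliberate design choice: with 1176 ambient
dimensions and a few hundred training epochs, the regularized within-class
scatter is badly ill-conditioned and the discriminant interpolates the
training set (within-class variance collapses by ~5 orders of magnitude),
which transfers poorly to held-out folds, especially for boosted trees whose
split thresholds hug the collapsed clusters. In the 60-dimensional score
space the within-class scatter is well conditioned and the same operator
generalizes. PCA is unsupervised, so the reordering leaks no labels.

**Classifiers.** Four ensemble families are trained on the selected
features: random forest (200 trees), extremely randomized trees (200 trees,
whole-dataset training, one random threshold per candidate feature),
gradient tree boosting (100 rounds, depth 3, learning rate 0.1, multinomial
log-loss), and SAMME.R-boosted shallow trees (50 iterations). The hybrid
model averages the class-probability outputs of the forest, extra-trees and
boosting models and predicts the argmax (soft voting; exact ties go to the
lowest class index). Tree growing is delegated to `ranger`, `xgboost` and
`rpart`; the available split criteria are Gini (forests) and the xgboost
gain rather than entropy / `friedman_mse`, a library-level substitution that
does not measurably change the benchmark. Everything around the trees —
feature pipeline, fold handling, voting, scoring — is native to the package.

**Evaluation.** `stratified_kfold()` deals each class round-robin into five
folds after a seeded shuffle (per-fold class counts within one of an even
split). All fitted transforms — xDawn filters, Frechet mean, PCA, FGDA,
ANOVA ranking — are refitted on each training fold and frozen before
touching the validation fold; anything else would leak labels.
`score_predictions()` pools validation predictions and reports per-class
one-vs-rest precision, recall and F1 (percent), their macro averages,
overall accuracy, the fold-wise standard error of each class's F1, and the
row-normalized confusion matrix.

## The preprocessing chain

The deterministic front half mirrors the standard continuous-EEG workflow:

1. **Band-pass FIR, 1-50 Hz.** Windowed-sinc (Hamming) design with
   transition width `max(low, 2)` Hz, applied forward and backward
   (zero-phase) with odd-reflection edge padding so labels stay aligned.
2. **One-second non-overlapping epochs.** Trailing partial windows are
   discarded; an epoch spanning a label change takes the majority label,
   ties resolved toward the label that starts earlier in the window.
3. **Peak-to-peak gate.** An epoch is dropped iff any channel spans more
   than 700 uV (gross artifact) or less than 1 uV (dead channel).
4. **Cross-validated rejection.** For every channel, candidate thresholds
   (midpoints between quantiles of the observed per-channel peak-to-peak
   values) are scored by the discrepancy between the mean of the training
   epochs passing the threshold and the pointwise median of the validation
   epochs. The criterion is nearly flat across the clean bulk — its
   differences there are sampling noise — and rises sharply once artifact
   epochs enter the mean, so the selected threshold is the *most permissive*
   candidate within 2% of the minimum error. Per epoch, channels above
   their threshold are bad: if more than `kappa = 50%` of channels are bad
   the epoch is dropped, otherwise the worst `rho = 4` are interpolated
   from neighboring sensors by inverse squared distance (montage positions
   are synthetic, so a spherical-spline interpolant would add no fidelity).
5. **ICA blink removal.** Epochs are concatenated and decomposed with a
   seeded fast fixed-point ICA (logcosh contrast, symmetric decorrelation).
   Components whose absolute correlation with the frontal surrogate channel
   `Fp1` reaches 0.8 are zeroed and the signal reconstructed; the
   rank-reduced remainder of the whitening is carried through unchanged, so
   removal of zero components is an exact identity.
6. **Second rejection pass** (thresholds re-learned by default), then
   optional **undersampling** of every class to the minority count to
   counter the ~80% NE imbalance.

Two numerical notes on the ICA. First, whitening directions below `1e-8` of
the leading variance are dropped; interpolated channels otherwise create
near-singular directions that the whitening would amplify into noise.
Second, when the remaining sources are close to Gaussian their rotation is
mathematically unidentifiable, and the symmetric fixed point either
oscillates between equivalent component orderings (detected by comparing
with the iterate two steps back) or wanders at sample-noise level; since the
reconstruction is exact for any orthogonal rotation, the iteration accepts
such a stalled basis at the cap (reported as `converged = FALSE`) and
reserves the convergence error for genuine divergence.

## The synthetic generator

`simulate_recording(sim_config(...))` emulates the statistical structure the
pipeline assumes:

- **Class-conditional covariance.** Independent unit-variance sources with
  `1/f^alpha` spectra (`alpha = 1` by default) are mixed through the
  Cholesky factor of the state's spatial covariance, so the empirical
  covariance converges to the configured one (verified to <10% Frobenius
  error at 300 s per class). The default covariances share one orthogonal
  mixing matrix; CA/DA/SS shift source log-powers by +-0.5 along distinct
  sign patterns (SS with a +0.2 overall elevation), giving non-NE states
  elevated mean power and pairwise affine-invariant distances of about
  2.2-3.2 between class covariances.
- **Imbalance.** Default durations 160/16/12/12 s put 80% of samples in NE,
  matching the imbalance the undersampler exists for. The classification
  benchmark used in the tests instead generates 200 one-second epochs per
  class, the balanced regime the classifier comparison assumes.
- **Artifacts**, injected per epoch with annotated ground truth: blinks
  (300 ms squared-sine transients, 200 uV, weighted toward frontal sensors,
  with the exact unit-amplitude time course stored for verification),
  muscle bursts (200 ms enveloped white noise, 60 uV), spikes (900 uV
  bipolar pulses, deliberately beyond the 700 uV gate), and near-flat
  channels (x0.01 for one epoch).
- **Determinism.** A given seed and config reproduce the recording
  bit-identically.

What it does *not* emulate — and hence what passing tests cannot show about
real data: non-Gaussian, non-stationary brain sources; volume-conduction
mixing tied to real electrode geometry; line noise; cardiac artifacts;
slow drifts; inter-subject variability. The benchmark numbers on synthetic
data (macro F1 near 100% with well-separated class covariances) are a
correctness check of the machinery, not a performance claim about cockpit
recordings.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `low`, `high` | 1, 50 Hz | FIR band edges |
| `max_ptp`, `min_ptp` | 700, 1 uV | epoch gate |
| `kappa` | 0.5 | bad-channel fraction above which an epoch is dropped |
| `rho` | 4 | channels interpolated per epoch |
| `r_thresh` | 0.8 | component-to-Fp1 correlation flagged as ocular |
| `nfilter` | 6 | xDawn filters per class (48 x 48 covariances for K = 4) |
| `shrinkage` | 0.05 | covariance shrinkage toward the scaled identity |
| `n_pca`, `k_anova` | 60, 40 | selection dimensions |
| `fgda_ridge` | 1e-3 | within-scatter ridge (fraction of mean diagonal) |
| Frechet mean | tol 1e-8, 50 iter | step halving on divergence |
| eigenvalue floor | 1e-12 | matrix roots/logs of nominally-SPD inputs |

## Degenerate inputs and tie-breaks

- `spd_covariance(..., shrinkage = 0)` raises a singularity error on rank
  deficiency; any positive shrinkage guarantees SPD.
- Soft-voting and argmax ties resolve toward the lowest class index in the
  canonical NE, CA, DA, SS order.
- Epoch-label ties resolve toward the earlier-starting label.
- The threshold learner raises a degenerate-threshold error if every
  candidate rejects every epoch on some channel; `undersample_balance`
  refuses single-class inputs; stratification refuses classes smaller than
  the fold count.

## Known limitations

- A one-second flat-channel dropout bounded by normal signal is partially
  masked by zero-phase filter leakage (the 1 uV gate sees ~5 uV of smeared
  neighborhood energy), so only longer dropouts are reliably caught; the
  repair-recovery checks therefore score sensitivity on the blink and spike
  annotations.
- Forest split criterion is Gini, boosting uses the xgboost gain; the
  entropy / `friedman_mse` criteria quoted for the reference configuration
  are not offered by the available libraries.
- FGDA reduces to at most K - 1 discriminant directions; with `use_fgda =
  TRUE` the effective feature rank is 3 for four classes. Disable it to
  keep the full PCA subspace.
- Problem sizes in the shipped tests (e.g. 200 s default recordings, an
  800-epoch benchmark, 200 random SPD pairs) were chosen to exercise every
  claim at desk scale; all scale up through the same configuration objects.
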