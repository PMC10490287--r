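# eegstate

An R package for detecting attention-related pilot mental states — normal
(NE), channelized attention (CA), diverted attention (DA) and
startle/surprise (SS) — from multichannel EEG. It implements the full chain
from raw continuous signal to a cross-validated classifier report:

- **Automated preprocessing**: zero-phase FIR band-pass (1–50 Hz),
  one-second epoching, peak-to-peak gating (700 µV / 1 µV),
  cross-validated per-channel rejection thresholds with neighbor
  interpolation, ICA blink removal using `Fp1` as a surrogate ocular
  channel, and class rebalancing by undersampling.
- **Riemannian features**: xDawn-augmented spatial covariance matrices
  (48 × 48 with the default 4 classes × 6 filters), mapped to the tangent
  space of the SPD manifold at the Fréchet mean — each matrix becomes a
  vector of length n(n+1)/2 = 1176 — then PCA, Fisher geodesic discriminant
  filtering, and ANOVA selection.
- **Hybrid ensemble classification**: random forest, extremely randomized
  trees, gradient tree boosting and SAMME.R AdaBoost under stratified
  5-fold cross-validation, plus a soft-voting hybrid over the first three;
  per-class precision/recall/F1 (with fold-wise standard errors), macro
  averages, and row-normalized confusion matrices.
- **Band-power topography**: Welch PSD per channel summarized in the delta
  (0–4), theta (4–8), alpha (8–12), beta (12–30) and gamma (30–45 Hz)
  bands, in dB.

The core geometry — distance, Fréchet mean, exponential/logarithmic maps
`Exp_P(S) = P^{1/2} exp(P^{-1/2} S P^{-1/2}) P^{1/2}`, isometric
vectorization — is exposed directly (`riemannian_distance()`,
`riemannian_mean()`, `exp_map()`, `log_map()`, `tangent_space()`).

A seeded synthetic generator (`simulate_recording()`) produces recordings
with known class-conditional spatial covariance, 1/f background spectra,
the ~80% NE class imbalance, and annotated blink/muscle/spike/flat
artifacts, so the whole pipeline runs and is verified without downloading
any archive. Real recordings in delimited text (one column per channel plus
a label column) load with `read_recording()`; to replicate at full scale,
point it at the public pilot-EEG CSV files and feed the result through the
same `preprocess_recording()` → `crossval_pipeline()` chain shown below.

## Worked example

```r
library(eegstate)

cfg <- sim_config(seed = 2024)          # 20 ch @ 256 Hz, 80% NE, artifacts
sim <- simulate_recording(cfg)
sim$recording
#> <eeg_recording> 20 channels x 51200 samples @ 256 Hz (200.0 s)
#> labels: NE=40960, CA=4096, DA=3072, SS=3072

pre <- preprocess_recording(sim$recording, seed = 2024)
pre$epochs
#> <eeg_epochs> 48 epochs x 20 channels x 256 samples @ 256 Hz
#> labels: NE=12, CA=12, DA=12, SS=12
#> flags: dropped=152, kept=45, repaired=3
```

The 200 raw epochs shrink to 48: gating and the two rejection passes remove
or repair the annotated artifacts, and undersampling then equalizes the
four classes at the minority count (12 each). The `flags` table keeps one
provenance row per original epoch (kept / repaired / dropped, with reason).

Cross-validated classification on a balanced artifact-free benchmark
(4 × 60 epochs here; the shipped tests use 4 × 200):

```r
cfg_b <- sim_config(class_durations = c(NE = 60, CA = 60, DA = 60, SS = 60),
                    artifacts = artifact_spec(0, 0, 0, 0, 0, 0, 0, 1),
                    seed = 2024)
eps <- epoch_fixed(bandpass_fir(simulate_recording(cfg_b)$recording))
cv <- crossval_pipeline(eps, families = c("rf", "gtb"),
                        vote = c("rf", "gtb"), seed = 2024)
cv$reports$voting
#> <state_report> accuracy 99.6%, macro F1 99.6%
#>   class precision recall    f1  se_f1
#> 1    NE     100.0   98.3  99.2 0.0087
#> 2    CA     100.0  100.0 100.0 0.0000
#> 3    DA     100.0  100.0 100.0 0.0000
#> 4    SS      98.4  100.0  99.2 0.0080
```

Each row is a one-vs-rest summary in percent; `se_f1` is the standard
deviation of that class's F1 across the five folds divided by √5. The
near-perfect scores reflect the generator's well-separated class
covariances (pairwise Riemannian distance ≥ 1), not expected performance on
real cockpit EEG. `tidy()`, `glance()` and `autoplot()` work on every
report, and `band_power(pre$epochs, "CA")` returns the per-channel band
powers as a tibble.

A thin command-line front end lives in `inst/cli/eegstate.R`
(`simulate`, `preprocess`, `features`, `train`, `spectra` subcommands).

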