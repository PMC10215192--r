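---
title: "EEG-EOG coupling and automatic sleep staging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-EOG coupling and automatic sleep staging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, and the design decisions taken where more
than one reasonable choice existed. It states no empirical numbers beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The question

Periocular electrodes record a mixture: the corneo-retinal dipole (the EOG
proper) plus volume-conducted frontal EEG. For automatic sleep staging from
EOG alone, that EEG contamination is not obviously noise — it may carry the
very spindle/slow-wave/alpha structure that defines the NREM stages. The
package operationalizes the question by *controlling* the amount of EEG
content in an EOG channel and measuring staging performance as a function of
that amount.

## Synthetic polysomnography

Real polysomnography corpora are access-restricted, so the package's study
runs on synthetic subjects with known ground truth. The generator emulates:

* **Hypnograms** from a first-order Markov chain over (W, N1, N2, N3, REM),
  30-s epochs, started at W. The default transition matrix is sticky
  (diagonal 0.6–0.8), giving plausible stage runs and occasional
  awakenings.
* **EEG sources** as sums of band-limited Gaussian noise — delta 0.5–4 Hz,
  theta 4–8 Hz, alpha 8–12 Hz, spindle-band 12–14 Hz — whose per-band
  amplitudes switch with the active stage, plus stage transients (75 µV
  half-sine slow waves in N3). The default stage signatures are stylized and
  deliberately well separated: alpha-dominant W, theta-dominant N1,
  spindle-dominant N2, delta-dominant N3, low-amplitude REM.
* **EOG sources** as slow (< 5 Hz) ocular drift plus transients: ±150 µV
  biphasic rapid-eye-movement deflections in REM, 200 µV blinks in W. The
  transient morphologies are stylized conventions, not fits to any corpus.
* **Mixing**: observed channels are an instantaneous linear mix,
  `X = A S + noise`. Each EOG channel receives 0.35/0.40 of the ipsilateral
  EEG source (so the *raw* EOG already carries EEG content, bracketing the
  raw correlations seen in clinical tables); each prefrontal EEG channel
  receives 0.1 of the ipsilateral EOG source.

Two generator choices deserve emphasis:

* **Hemispheric asymmetry is required for identifiability.** Second-order
  blind separation can only distinguish sources with *distinct* lagged
  autocovariance (equivalently, spectral) structure. If the left and right
  EEG sources had identical band profiles, any rotation of that pair would
  be an equally valid solution and per-source recovery would be undefined.
  The generator therefore scales the right EEG source's band amplitudes
  (×0.8 delta, ×1.3 theta, ×0.7 alpha, ×1.15 spindle) and gives the two
  ocular drifts different low-frequency bands (0.3–2 Hz vs 0.8–4 Hz) — a
  stylized counterpart of the left/right spectral differences in real
  recordings.
* **What passing tests do and do not show.** The synthetic stages are
  strongly separable by construction and the mixing is exactly
  instantaneous and linear. Success here validates the *implementation* —
  calibration exactness, separation correctness, learnability, metric
  definitions — not clinical-grade staging accuracy; real EEG has
  within-stage variability, non-stationary artifacts, and frequency-
  dependent coupling that the generator deliberately omits.

Defaults: generation at 256 Hz (so the resample-to-128 Hz stage is exercised
non-trivially), 240 epochs (2 h) per subject, 6 subjects in the default
cohort — sized so that the full end-to-end sweep completes comfortably on a
single CPU; all randomness flows from one per-subject seed.

## Conditioning

* Notch: an RBJ biquad at 50/60 Hz with quality factor 30, applied
  zero-phase (forward-backward with reflect padding). Verified to keep the
  passband within ±1 dB outside ±2 Hz of the line frequency.
* Band-pass 0.3–35 Hz: a cascade of a 2nd-order Butterworth high-pass and a
  7th-order low-pass, each zero-phase. A single direct-form band-pass with a
  0.3 Hz edge at fs 256 is numerically fragile, and lower low-pass orders
  cannot simultaneously hold the 1–30 Hz passband within ±1 dB and provide
  ≥ 20 dB at 45 Hz under zero-phase (squared-magnitude) application; order
  7 satisfies both with margin.
* Resampling: rational polyphase (ratio reduced to lowest terms,
  zero-stuffing, Hamming-windowed sinc anti-alias FIR, decimation) with the
  FIR group delay compensated exactly, so resampled signals stay
  sample-aligned with analytic references.
* Epoching: 30 s × 128 Hz = 3840 samples per epoch; a trailing partial
  epoch is dropped; a label/epoch count mismatch warns and truncates to the
  shorter.

Zero-phase filtering everywhere avoids shifting stage boundaries; the first
and last seconds of a recording carry the usual reflect-padding edge
transients and are excluded from the package's own filter-response
assertions.

## SOBI

The separation chain is: per-channel standardization → symmetric whitening
M = C^(-1/2) (so M = I for already-white input) → lagged covariances
R(τ) = E[Z(t+τ)Z(t)ᵀ], symmetrized, for τ = 1…100 samples at 128 Hz
(≈ 8 ms–0.8 s of autocorrelation structure; the classical ranges for sleep
EEG rhythms) → joint approximate diagonalization by Jacobi-style sweeps of
Givens rotations, each rotation angle chosen to maximally reduce the summed
squared off-diagonal mass (the angle reduces to the classical Jacobi angle
for a single matrix); convergence when every rotation in a sweep is below
1e-8 radians, at most 200 sweeps → S = Uᵀ Z.

Decisions:

* **All four channels enter the separation jointly** (Fp1, Fp2, E1, E2):
  the ocular reference must be in the mix for ocular components to be
  isolable.
* **Component ordering** is by descending back-projected variance with a
  deterministic sign fix (largest-magnitude mixing loading positive), so
  results are reproducible up to this documented ordering.
* **Ocular components** are those whose absolute correlation with either
  reference EOG channel reaches 0.7 (configurable). Removing every
  component is refused with an error (the threshold is too low). The clean
  EEG is the back-projection of the remaining components onto Fp1/Fp2 with
  the original scale and offset restored.
* **Degenerate inputs**: temporally white sources are not identifiable from
  second-order statistics. The fit flags this (`low_contrast`) by comparing
  the energy of the lagged covariances against their sampling-noise floor
  (≈ m²/N per matrix) rather than failing.

## Correlation-calibrated coupling

With c = cov(raw, clean), u = var(raw), v = var(clean), the calibration
condition corr(raw + a·clean, clean) = ρ squares to

v²(1−ρ²)·a² + 2cv(1−ρ²)·a + (c² − ρ²uv) = 0.

Squaring introduces a sign-spurious root, so each real root is checked
against the achieved correlation; among matching roots the smallest |a| is
returned — the minimal perturbation of the raw signal, consistent with the
observation that the least-changed signal sits at the target nearest the
raw correlation. ρ = 0 is the double-root case a = −c/v (the discriminant
is analytically zero and is clamped against round-off); it *subtracts* the
EEG content already present, which is this package's convention for the
"clean EOG" condition. Correlation is computed over the whole recording,
matching a single per-subject content value; per-epoch calibration is
deliberately out of scope.

## The staging network

Input is a sequence of L epochs × 3840 samples of a single channel,
standardized per recording (per-recording rather than per-epoch, so that
between-stage amplitude differences remain informative). Defaults:

| parameter | default | meaning |
|---|---|---|
| small kernel / stride | 64 / 8 samples | 0.5 s span — waveform-scale features |
| large kernel / stride | 640 / 64 samples | 5 s span — rhythm-scale features |
| filters per branch | 32 | |
| pooling | global average ‖ global max | 128 features per epoch |
| Bi-GRU hidden | 32 per direction | sequence context over epochs |
| sequence length L | 20 epochs (10 min) | training window |
| loss | class-weighted cross-entropy | inverse stage frequency (N1 scarcity) |
| optimizer | Adam, lr 1e-3, batch 8 sequences | |
| dropout | 0 (configurable) | |

Each branch is a single convolution followed by ReLU and global
average+max pooling. A stacked second convolution at the same kernel
length cannot exist in the large branch (its first-layer output, 51
positions, is shorter than a 640-tap kernel), so the default architecture
uses one convolution per branch and keeps the two published kernel spans;
depth is configurable. The residual connection projects the concatenated
CNN features to the Bi-GRU output width (64) with a learned linear map and
adds them before the dense softmax. Ties in the arg-max prediction break
toward the lower stage index, deterministically.

The implementation is plain R: convolutions as im2col matrix products
(BLAS), backpropagation through time derived by hand and verified against
finite differences in the test suite, Adam from its defining equations.
Training is fully seeded (initialization, batch shuffling, dropout) and
exactly reproducible on fixed hardware.

## Evaluation protocol

Leave-one-subject-out: each subject is the test set exactly once;
train/test subject-disjointness is asserted per fold. Metrics are computed
on the pooled test epochs (per-subject mean accuracy is reported
alongside, since pooled vs averaged is a genuine reporting ambiguity):
accuracy, Cohen's kappa from the confusion marginals, macro F1 over stages
present in the truth, macro specificity (mean TN/(TN+FP)), and per-stage
precision (0, with a note, for stages never predicted).

The chi-square analysis discretizes each per-epoch network feature (the
concatenated CNN feature vector) into 10 quantile bins, merges adjacent
bins until expected counts reach 5 (stopping at two bins — with a rare
stage the classical ≥ 5 rule can be unattainable by bin-merging alone, in
which case the statistic is reported with a note), and tests independence
against the stage labels. Per-feature p-values are reported with a
Bonferroni-adjusted minimum and a mean-statistic summary. Its null
calibration (rejection rate ≈ α for independent features) is verified in
the test suite.

## Problem sizes

The default cohort (6 subjects × 240 epochs, 5 training epochs per LOSO
fold) is the package's standard benchmark: large enough that all five
stages appear in every training split and the ρ-sweep produces a stable
profile, small enough to iterate on a laptop. The SOBI recovery and
cleanup checks use 20 subjects of 30 epochs (separation quality is driven
by sample count per epoch, not night length). These sizes are the
package's own choices and are configurable throughout.

## Known limitations

* The generator's linear instantaneous mixing cannot probe
  frequency-dependent or time-varying coupling.
* Stage signatures are stylized; N1 in particular is far harder in real
  data than here.
* The staging network is sized for CPU training on the synthetic
  benchmark; matching clinical-corpus accuracies would require full-night
  cohorts and longer training than the defaults.
* EDF support covers continuous 16-bit recordings with integer sampling
  rates and a single rate across channels — sufficient for the package's
  pipeline, not a general EDF+ implementation.
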