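# eogcoupling

Automatic sleep staging is usually built on EEG, but the electrooculogram
(EOG) is far easier to record — and every recorded EOG inevitably contains a
fraction of frontal EEG, volume-conducted into the periocular electrodes.
`eogcoupling` implements an end-to-end protocol for asking a precise
question about that contamination: **how does the amount of EEG content
coupled into an EOG channel affect the accuracy of automatic sleep
staging?**

The package is aimed at sleep/biosignal researchers who want to study
EEG–EOG cross-coupling with full control of the ground truth. Because
clinical polysomnography corpora are access-restricted, the package ships a
synthetic polysomnography generator with known latent sources, known mixing,
and stage-dependent spectral signatures, so that every stage of the protocol
is testable against a known answer.

## The method

1. **Conditioning** — each channel (Fp1, Fp2, left/right EOG) is notch
   filtered (50/60 Hz), band-passed to 0.3–35 Hz, and resampled to 128 Hz.
2. **Source separation (SOBI)** — second-order blind identification:
   normalize X₀ ← X, whiten Z ← M X₀, estimate time-lagged covariances
   R(τ) = E[Z(t+τ) Z(t)ᵀ], find one orthogonal U that jointly
   (approximately) diagonalizes all R(τ) by Givens-rotation sweeps, and
   reconstruct sources S = Uᵀ Z. Components correlated with the EOG
   reference above a threshold are removed and the remainder back-projected,
   giving the ocular-free `cleanEEG`.
3. **Correlation-calibrated coupling** — coupled EOG signals are built as

       coupledEOG = rawEOG + a · cleanEEG

   with the superposition factor `a` solved in closed form (a quadratic in
   `a`) so that `corr(coupledEOG, cleanEEG)` hits each target level in
   {0.0, 0.1, 0.2, 0.3, 0.5}. The target-0 case *removes* the EEG content
   already present in the raw EOG (negative `a`). The perturbation of the
   raw signal is quantified by the mean absolute error (MAE).
4. **Staging network** — a two-scale 1-D CNN (kernels of 64 and 640 samples,
   i.e. 0.5 s and 5 s at 128 Hz) extracts per-epoch features F = [F₁ ‖ F₂],
   a bidirectional GRU learns the epoch-sequence structure H = GRU(F), a
   residual connection adds the CNN features back (O = H + W F), and a dense
   softmax outputs per-epoch probabilities over the five AASM stages
   (W, N1, N2, N3, REM). Implemented natively in R (BLAS convolutions,
   hand-derived backpropagation through time, Adam).
5. **Evaluation** — leave-one-subject-out cross-validation per signal
   condition (each coupled target, the raw EOG, the clean EEG), with
   accuracy, Cohen's kappa, macro F1, macro specificity, per-stage
   precision, and a chi-square significance analysis between the network's
   features and the stage labels.

## Worked example

```r
library(eogcoupling)

subj <- make_synthetic_subject("S1", n_epochs = 60, seed = 42)
rec  <- preprocess_recording(subj$recording)        # notch, 0.3-35 Hz, 128 Hz
sep  <- sobi(rec)                                   # blind source separation
clean <- remove_eog_components(sep, rec$samples[c("E1", "E2"), ], fs = 128)

cs <- build_coupled_set(channel(rec, "E1"), channel(clean, "Fp1"))
print(cs)
```

```
<coupled_eog_set> raw EOG ~ clean EEG correlation: 0.2037
 target_rho         a achieved_rho mae_vs_raw
        0.0 -0.345007   -5.622e-18     5.8344
        0.1 -0.178345    1.000e-01     3.0160
        0.2 -0.006515    2.000e-01     0.1102
        0.3  0.176494    3.000e-01     2.9847
        0.5  0.612393    5.000e-01    10.3562
```

Reading: the raw left EOG of this synthetic subject already carries EEG
content (correlation 0.20 with the clean Fp1 signal). Each row calibrates
the superposition factor `a` so the coupled signal hits its target
correlation exactly (to 1e-6 and better); the MAE column shows that the
smallest change to the raw EOG (0.11 µV) occurs at the target closest to
the raw correlation, and that forcing a fully "clean" EOG (target 0.0)
perturbs the signal more (5.8 µV) than moderate re-coupling.

The full study — simulate a cohort, separate, couple, and run the
leave-one-subject-out staging sweep over all signal conditions — is one
call:

```r
res <- run_experiment(experiment_config(seed = 1))
print(res)   # coupling table, per-condition metric suite, significance table
```

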