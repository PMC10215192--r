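# Shared fixtures. Expensive pipeline objects (generated subjects, SOBI
# fits) are memoized in an environment so that multiple test files can reuse
# them without recomputation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# A small subject pushed through the conditioning + separation pipeline.
fixture_pipeline <- function(seed, n_epochs = 30) {
  memo(sprintf("pipe_%d_%d", seed, n_epochs), {
    subj <- make_synthetic_subject(paste0("S", seed), n_epochs = n_epochs,
                                   seed = seed)
    rec <- preprocess_recording(subj$recording)
    sep <- sobi(rec)
    clean <- remove_eog_components(sep, rec$samples[c("E1", "E2"), ,
                                                    drop = FALSE], fs = 128)
    src128 <- resample_recording(
      psg_recording(subj$latent_sources, subj$recording$fs,
                    rownames(subj$latent_sources)), 128)
    list(subject = subj, rec = rec, sep = sep, clean = clean,
         sources128 = src128)
  })
}

# Permutation/sign-matched absolute correlations between estimated and true
# source matrices (greedy assignment on the absolute correlation matrix).
matched_source_correlations <- function(S_est, S_true) {
  cm <- abs(stats::cor(t(S_est), t(S_true)))
  out <- numeric(0)
  while (length(cm) && nrow(cm) >= 1 && ncol(cm) >= 1) {
    k <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    out <- c(out, cm[k[1], k[2]])
    cm <- cm[-k[1], -k[2], drop = FALSE]
  }
  out
}

# Labelled epoch matrix for the staging tests: sources generated directly at
# 128 Hz (no conditioning needed for network-only tests).
fixture_epochs <- function(seed, n_epochs = 40) {
  memo(sprintf("ep_%d_%d", seed, n_epochs), {
    hyp <- make_hypnogram(n_epochs, seed = seed)
    S <- synthesize_sources(hyp, fs = 128, seed = seed + 1L)
    rec <- mix_channels(S, default_mixing_model(), seed = seed + 2L)
    ep <- epoch_segment(rec, hyp, subject_id = paste0("S", seed))
    list(x = ep$epochs[["Fp1"]], y = match(ep$labels, c("W", "N1", "N2", "N3", "REM")),
         eog = ep$epochs[["E1"]], labels = ep$labels)
  })
}

STAGES5 <- c("W", "N1", "N2", "N3", "REM")
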