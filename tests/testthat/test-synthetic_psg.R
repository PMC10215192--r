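test_that("hypnogram sampling follows the transition matrix", {
  # absorbing chain started at W stays in W
  hyp <- make_hypnogram(10, diag(5), seed = 1)
  expect_equal(hyp$labels, rep("W", 10))

  # uniform chain: stage frequencies converge to 1/5
  tm <- matrix(0.2, 5, 5)
  hyp <- make_hypnogram(50000, tm, seed = 2)
  freq <- table(factor(hyp$labels, levels = STAGES5)) / 50000
  expect_true(all(abs(freq - 0.2) < 0.01))

  # determinism
  expect_identical(make_hypnogram(100, seed = 7)$labels,
                   make_hypnogram(100, seed = 7)$labels)

  # non-stochastic matrix names the offending row
  bad <- default_transitions(); bad[3, 1] <- bad[3, 1] + 0.1
  expect_error(make_hypnogram(10, bad), "row 3")
})

test_that("stage frequencies converge to the chain's stationary distribution", {
  tm <- default_transitions()
  # stationary distribution from the left eigenvector
  e <- eigen(t(tm))
  k <- which.min(abs(e$values - 1))
  pi_stat <- Re(e$vectors[, k]); pi_stat <- pi_stat / sum(pi_stat)
  hyp <- make_hypnogram(10000, tm, seed = 11)
  # the sticky chain's draws are autocorrelated, which invalidates the
  # multinomial chi-square; thin to every 50th epoch (well past the mixing
  # time) so the goodness-of-fit test is calibrated
  thin <- hyp$labels[seq(1, 10000, by = 50)]
  obs <- as.numeric(table(factor(thin, levels = STAGES5)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = pi_stat))
  expect_gt(gof$p.value, 0.001)
  # raw frequencies still match the stationary distribution closely
  freq <- as.numeric(table(factor(hyp$labels, levels = STAGES5))) / 10000
  expect_lt(max(abs(freq - pi_stat)), 0.05)
})

test_that("synthesized sources have stage-dependent band power", {
  # N3-only hypnogram with only delta and spindle content
  cfgs <- default_stage_configs()
  cfgs$N3 <- stage_config("N3", c(delta = 40, theta = 0, alpha = 0, spindle = 2),
                          transient_rate = 0, eog_drift_sd = 0)
  hyp <- hypnogram(rep("N3", 20))
  S <- synthesize_sources(hyp, fs = 128, configs = cfgs, seed = 3)
  x <- S["EEG_left", ]
  # periodogram band-power oracle
  band_power <- function(x, fs, lo, hi) {
    sp <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) / length(x) * fs
    sum(sp[f >= lo & f <= hi])
  }
  ratio <- band_power(x, 128, 0.5, 4) / band_power(x, 128, 12, 14)
  expect_gt(ratio, (40 / 2)^2 * 0.8)
  expect_lt(ratio, (40 / 2)^2 * 1.2)

  # band-power ordering across stages: N3 delta-dominant, W alpha-dominant
  hyp2 <- hypnogram(c(rep("N3", 10), rep("W", 10)))
  S2 <- synthesize_sources(hyp2, fs = 128, seed = 4)
  x2 <- S2["EEG_left", ]
  n3 <- x2[1:(10 * 30 * 128)]; w <- x2[-(1:(10 * 30 * 128))]
  expect_gt(band_power(n3, 128, 0.5, 4), band_power(n3, 128, 8, 12))
  expect_gt(band_power(w, 128, 8, 12), band_power(w, 128, 0.5, 4))
})

test_that("REM transient counts follow the configured rate", {
  hyp <- hypnogram(rep("REM", 40))     # 20 min
  S <- synthesize_sources(hyp, fs = 128, seed = 5)
  ev <- attr(S, "events")
  n_em <- sum(ev$type == "eye_movement" & ev$source == "EOG_left")
  lambda <- default_stage_configs()$REM$transient_rate * 40 * 0.5
  expect_gt(n_em, lambda - 4 * sqrt(lambda))
  expect_lt(n_em, lambda + 4 * sqrt(lambda))
})

test_that("all-zero configuration produces all-zero sources", {
  cfgs <- lapply(STAGES5, function(s)
    stage_config(s, c(delta = 0, theta = 0, alpha = 0, spindle = 0),
                 transient_rate = 0, eog_drift_sd = 0))
  names(cfgs) <- STAGES5
  S <- synthesize_sources(hypnogram(rep("N2", 3)), fs = 128,
                          configs = cfgs, seed = 1)
  expect_equal(max(abs(S)), 0)
})

test_that("sources are de-meaned per epoch and configs validated", {
  hyp <- make_hypnogram(6, seed = 2)
  S <- synthesize_sources(hyp, fs = 128, seed = 2)
  P <- 30 * 128
  for (i in seq_len(6)) {
    seg <- S[, (i - 1) * P + seq_len(P)]
    expect_true(all(abs(rowMeans(seg)) < 1))
  }
  expect_error(synthesize_sources(hyp, fs = 128,
                                  configs = default_stage_configs()[1:4]),
               "missing stage config")
  expect_error(synthesize_sources(hyp, fs = 50), "fs must be")
})

test_that("channel mixing is the stated linear model", {
  hyp <- hypnogram(rep("N2", 4))
  S <- synthesize_sources(hyp, fs = 128, seed = 9)

  # identity mixing, no noise: observed equals sources
  mm <- mixing_model(diag(4), noise_sd = 0)
  rec <- mix_channels(S, mm, seed = 1)
  expect_equal(unname(rec$samples), unname(S[, ]), tolerance = 1e-12)

  # analytic correlation of a linear mix vs sample correlation
  A <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0.3, 0, 1, 0), c(0, 0, 0, 1))
  rec2 <- mix_channels(S, mixing_model(A, noise_sd = 0), seed = 1)
  e1 <- rec2$samples[3, ]
  v_eeg <- stats::var(S["EEG_left", ]); v_eog <- stats::var(S["EOG_left", ])
  cv <- stats::cov(S["EEG_left", ], S["EOG_left", ])
  rho_analytic <- (0.3 * v_eeg + cv) /
    sqrt(v_eeg * (0.09 * v_eeg + v_eog + 2 * 0.3 * cv))
  expect_equal(stats::cor(e1, S["EEG_left", ]), rho_analytic,
               tolerance = 1e-10)

  # determinism with noise
  mmn <- default_mixing_model(noise_sd = 2)
  expect_identical(mix_channels(S, mmn, seed = 4)$samples,
                   mix_channels(S, mmn, seed = 4)$samples)

  # shape mismatch
  expect_error(mix_channels(S[1:3, ], default_mixing_model()), "columns")
})

test_that("mixing matrix is recoverable by least squares without noise", {
  subj <- make_synthetic_subject("rec", n_epochs = 4, fs = 128,
                                 mixing = default_mixing_model(noise_sd = 0),
                                 seed = 21)
  A_hat <- t(stats::lsfit(t(subj$latent_sources), t(subj$recording$samples),
                          intercept = FALSE)$coefficients)
  A <- subj$mixing$mixing_matrix
  expect_lt(max(abs(A_hat - A)) / max(abs(A)), 1e-8)
})

test_that("subject generation is reproducible and internally consistent", {
  s1 <- make_synthetic_subject("a", n_epochs = 3, fs = 128, seed = 5)
  s2 <- make_synthetic_subject("a", n_epochs = 3, fs = 128, seed = 5)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$hypnogram$labels, s2$hypnogram$labels)
  # duration invariant: recording length = epochs x epoch samples
  expect_equal(ncol(s1$recording$samples), 3 * 30 * 128)
  expect_equal(ncol(s1$latent_sources), ncol(s1$recording$samples))
})
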