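# Synthetic polysomnography with known latent sources and known EEG<->EOG
# mixing. Every downstream stage (preprocessing, source separation, coupling,
# staging) is testable against this ground truth without gated clinical data.

SOURCE_LABELS <- c("EEG_left", "EEG_right", "EOG_left", "EOG_right")
BAND_EDGES <- list(delta = c(0.5, 4), theta = c(4, 8),
                   alpha = c(8, 12), spindle = c(12, 14))

#' Stage-specific spectral configuration
#'
#' Describes the latent-source signal model for one sleep stage: relative
#' amplitudes of band-limited noise in the classical EEG bands, the rate of
#' the stage's characteristic transient (slow waves in N3, rapid eye movements
#' in REM, blinks in W), and the amplitude of the slow ocular drift that makes
#' up the EOG background.
#'
#' @param stage one of `W, N1, N2, N3, REM`.
#' @param band_powers named numeric vector with entries `delta` (0.5-4 Hz),
#'   `theta` (4-8 Hz), `alpha` (8-12 Hz), `spindle` (12-14 Hz): amplitude
#'   (standard deviation, microvolts) of each band-limited noise component in
#'   the EEG sources. All must be >= 0.
#' @param transient_rate events per minute of the stage's transient (>= 0).
#' @param eog_drift_sd standard deviation (microvolts) of the slow (< 5 Hz)
#'   ocular drift in the EOG sources during this stage.
#' @return a `stage_config` list.
#' @export
stage_config <- function(stage, band_powers, transient_rate = 0,
                         eog_drift_sd = 40) {
  stage <- match.arg(stage, STAGES)
  need <- names(BAND_EDGES)
  if (!all(need %in% names(band_powers)))
    stopf("band_powers must name all of: %s", paste(need, collapse = ", "))
  band_powers <- band_powers[need]
  if (any(band_powers < 0)) stopf("band amplitudes must be >= 0")
  if (transient_rate < 0) stopf("transient_rate must be >= 0")
  if (eog_drift_sd < 0) stopf("eog_drift_sd must be >= 0")
  structure(list(stage = stage, band_powers = band_powers,
                 transient_rate = transient_rate,
                 eog_drift_sd = eog_drift_sd),
            class = "stage_config")
}

#' Default stage spectral configurations
#'
#' Stylized but clearly separated stage signatures: alpha-dominant wake with
#' blinks, theta-dominant N1, spindle-band-dominant N2, delta-dominant N3 with
#' slow waves, and low-amplitude mixed-frequency REM with rapid eye movements.
#' Amplitudes are in microvolts and are deliberately well separated so that
#' recovery of the staging structure is identifiable by construction; they do
#' not claim the full within-stage variability of clinical data.
#'
#' @return named list of `stage_config` objects, one per stage.
#' @export
default_stage_configs <- function() {
  list(
    W   = stage_config("W",   c(delta = 6,  theta = 4,  alpha = 22, spindle = 2),
                       transient_rate = 4,  eog_drift_sd = 40),
    N1  = stage_config("N1",  c(delta = 8,  theta = 18, alpha = 6,  spindle = 2),
                       transient_rate = 0,  eog_drift_sd = 35),
    N2  = stage_config("N2",  c(delta = 14, theta = 8,  alpha = 4,  spindle = 16),
                       transient_rate = 0,  eog_drift_sd = 30),
    N3  = stage_config("N3",  c(delta = 40, theta = 6,  alpha = 2,  spindle = 2),
                       transient_rate = 8,  eog_drift_sd = 25),
    REM = stage_config("REM", c(delta = 5,  theta = 8,  alpha = 4,  spindle = 1),
                       transient_rate = 10, eog_drift_sd = 35)
  )
}

#' Linear instantaneous mixing model
#'
#' Observed channels are an instantaneous linear mix of the latent sources
#' plus Gaussian sensor noise. The default couples 0.35 (left) / 0.40 (right)
#' of the ipsilateral EEG source into each EOG channel and 0.1 of the
#' ipsilateral EOG source into each prefrontal EEG channel.
#'
#' @param mixing_matrix observed-channel x latent-source weight matrix; must
#'   have full column rank.
#' @param noise_sd additive sensor noise standard deviation (microvolts, >= 0).
#' @param channel_labels ordered observed-channel labels.
#' @return a `mixing_model` list.
#' @export
mixing_model <- function(mixing_matrix, noise_sd = 2,
                         channel_labels = c("Fp1", "Fp2", "E1", "E2")) {
  mixing_matrix <- as.matrix(mixing_matrix)
  if (nrow(mixing_matrix) != length(channel_labels))
    stopf("mixing matrix has %d rows but %d channel labels",
          nrow(mixing_matrix), length(channel_labels))
  if (qr(mixing_matrix)$rank < ncol(mixing_matrix))
    stopf("mixing matrix must have full column rank")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  dimnames(mixing_matrix) <- list(channel_labels,
                                  SOURCE_LABELS[seq_len(ncol(mixing_matrix))])
  structure(list(mixing_matrix = mixing_matrix, noise_sd = noise_sd,
                 channel_labels = channel_labels),
            class = "mixing_model")
}

#' @rdname mixing_model
#' @export
default_mixing_model <- function(noise_sd = 2) {
  A <- rbind(Fp1 = c(1,    0,    0.10, 0),
             Fp2 = c(0,    1,    0,    0.10),
             E1  = c(0.35, 0,    1,    0),
             E2  = c(0,    0.40, 0,    1))
  mixing_model(A, noise_sd = noise_sd)
}

#' Sample a hypnogram from a first-order Markov chain
#'
#' Draws `n_epochs` stage labels from the chain defined by a 5x5
#' row-stochastic transition matrix over (W, N1, N2, N3, REM), started at W.
#'
#' @param n_epochs number of 30-s epochs (>= 1).
#' @param transition_matrix 5x5 matrix; rows must sum to 1 within 1e-9.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param epoch_seconds epoch length in seconds.
#' @return a [hypnogram].
#' @export
make_hypnogram <- function(n_epochs, transition_matrix = default_transitions(),
                           seed = 1, epoch_seconds = 30) {
  if (n_epochs < 1) stopf("n_epochs must be >= 1")
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(5L, 5L))) stopf("transition matrix must be 5x5")
  rs <- rowSums(tm)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad))
    stopf("transition matrix row %d (stage %s) sums to %.12g, not 1",
          bad[1], STAGES[bad[1]], rs[bad[1]])
  if (any(tm < 0)) stopf("transition probabilities must be >= 0")
  labels <- with_seed(seed, {
    out <- integer(n_epochs)
    state <- 1L  # start in W
    for (i in seq_len(n_epochs)) {
      out[i] <- state
      state <- sample.int(5L, 1L, prob = tm[state, ])
    }
    out
  })
  hypnogram(STAGES[labels], epoch_seconds = epoch_seconds)
}

#' Default sleep-stage transition matrix
#'
#' A sticky chain with plausible night architecture: long N2/N3/REM runs,
#' brief N1, and occasional awakenings. Rows/columns ordered (W, N1, N2, N3,
#' REM).
#' @return 5x5 row-stochastic matrix.
#' @export
default_transitions <- function() {
  tm <- rbind(W   = c(0.80, 0.15, 0.02, 0.01, 0.02),
              N1  = c(0.05, 0.60, 0.30, 0.01, 0.04),
              N2  = c(0.01, 0.05, 0.75, 0.12, 0.07),
              N3  = c(0.01, 0.02, 0.15, 0.80, 0.02),
              REM = c(0.03, 0.05, 0.10, 0.01, 0.81))
  colnames(tm) <- STAGES
  tm
}

# Band-limited Gaussian noise of unit variance: white noise -> zero-phase
# 4th-order Butterworth band-pass -> rescale to sd 1.
band_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- filtfilt_reflect(bf$b, bf$a, x)
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# Stage transient waveforms (microvolts), sampled at fs.
transient_wave <- function(type, fs) {
  switch(type,
    slow_wave = 75 * sin(pi * seq(0, 1, length.out = round(fs * 1.0))),
    eye_movement = {
      # biphasic ramp: +150 then -150 over 0.5 s
      n <- round(fs * 0.5); h <- ceiling(n / 2)
      150 * c(seq(0, 1, length.out = h), seq(1, -1, length.out = n - h),
              0)[seq_len(n)]
    },
    blink = 200 * exp(-((seq_len(round(fs * 0.3)) - round(fs * 0.15))^2) /
                        (2 * (fs * 0.05)^2)),
    stopf("unknown transient type '%s'", type))
}

stage_transient_type <- c(W = "blink", N1 = "", N2 = "",
                          N3 = "slow_wave", REM = "eye_movement")

# Draw Poisson transient events for each epoch of the hypnogram and add the
# waveform into `x` (modified copy returned). Returns list(x, events).
add_transients <- function(x, hyp, fs, configs, which_type, source_label) {
  ep_len <- hyp$epoch_seconds * fs
  events <- list()
  for (i in seq_along(hyp$labels)) {
    st <- hyp$labels[i]
    type <- stage_transient_type[[st]]
    if (!nzchar(type) || type != which_type) next
    rate <- configs[[st]]$transient_rate
    if (rate <= 0) next
    k <- stats::rpois(1, rate * hyp$epoch_seconds / 60)
    if (k == 0) next
    wave <- transient_wave(type, fs)
    sign_flip <- if (type == "eye_movement") sample(c(-1, 1), k, TRUE)
                 else rep(1, k)
    starts <- (i - 1L) * ep_len +
      sort(sample.int(max(1L, ep_len - length(wave)), k, replace = TRUE))
    for (j in seq_len(k)) {
      idx <- starts[j] + seq_along(wave) - 1L
      idx <- idx[idx <= length(x)]
      x[idx] <- x[idx] + sign_flip[j] * wave[seq_along(idx)]
    }
    events[[length(events) + 1L]] <-
      data.frame(source = source_label, stage = st, type = type,
                 epoch = i, sample = starts)
  }
  list(x = x, events = events)
}

#' Synthesize latent EEG and EOG sources for a hypnogram
#'
#' EEG sources (`EEG_left`, `EEG_right`) are sums of band-limited Gaussian
#' noise whose per-band amplitude follows the active stage's `band_powers`,
#' plus stage transients (N3 slow waves). EOG sources (`EOG_left`,
#' `EOG_right`) are slow (0.3-4 Hz) ocular drift whose amplitude follows the
#' stage's `eog_drift_sd`, plus stage transients (REM eye movements, W
#' blinks). All four sources are statistically independent and each is
#' de-meaned per epoch.
#'
#' Second-order blind separation is only identifiable when sources have
#' distinct lagged-covariance (i.e. spectral) structure, so the generator
#' builds in a hemispheric asymmetry: the right EEG source's band amplitudes
#' are scaled by `eeg_asymmetry`, and the two EOG drifts occupy different
#' (overlapping) low-frequency bands — a stylized counterpart of the
#' left/right spectral differences present in real recordings.
#'
#' @param hyp a [hypnogram].
#' @param fs sampling rate in Hz (>= 100).
#' @param configs named list of [stage_config] covering all five stages.
#' @param seed integer seed.
#' @param eeg_asymmetry per-band amplitude multipliers applied to the right
#'   EEG source.
#' @param eog_drift_bands drift frequency band (Hz) per EOG source.
#' @return 4 x N numeric matrix with rownames
#'   `EEG_left, EEG_right, EOG_left, EOG_right`; attribute `events` holds a
#'   data frame of the generated transient events (source, stage, type,
#'   epoch, start sample).
#' @export
synthesize_sources <- function(hyp, fs = 256,
                               configs = default_stage_configs(), seed = 1,
                               eeg_asymmetry = c(delta = 0.8, theta = 1.3,
                                                 alpha = 0.7, spindle = 1.15),
                               eog_drift_bands = list(
                                 EOG_left = c(0.3, 2),
                                 EOG_right = c(0.8, 4))) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (fs < 100) stopf("fs must be >= 100 Hz")
  missing <- setdiff(STAGES, names(configs))
  if (length(missing))
    stopf("missing stage config(s): %s", paste(missing, collapse = ", "))
  ep_len <- hyp$epoch_seconds * fs
  if (ep_len != round(ep_len)) stopf("epoch length must be a whole number of samples")
  n <- length(hyp$labels) * ep_len
  # per-sample amplitude envelope for a named per-stage scalar
  envelope <- function(get) {
    v <- vapply(hyp$labels, get, numeric(1))
    rep(v, each = ep_len)
  }
  with_seed(seed, {
    S <- matrix(0, nrow = 4, ncol = n, dimnames = list(SOURCE_LABELS, NULL))
    all_events <- list()
    for (src in c("EEG_left", "EEG_right")) {
      x <- numeric(n)
      for (b in names(BAND_EDGES)) {
        gain <- if (src == "EEG_right") eeg_asymmetry[[b]] else 1
        env <- gain * envelope(function(st) configs[[st]]$band_powers[[b]])
        if (all(env == 0)) next
        x <- x + env * band_noise(n, fs, BAND_EDGES[[b]])
      }
      tr <- add_transients(x, hyp, fs, configs, "slow_wave", src)
      S[src, ] <- tr$x
      all_events <- c(all_events, tr$events)
    }
    for (src in c("EOG_left", "EOG_right")) {
      env <- envelope(function(st) configs[[st]]$eog_drift_sd)
      x <- if (all(env == 0)) numeric(n)
           else env * band_noise(n, fs, eog_drift_bands[[src]])
      for (type in c("eye_movement", "blink")) {
        tr <- add_transients(x, hyp, fs, configs, type, src)
        x <- tr$x
        all_events <- c(all_events, tr$events)
      }
      S[src, ] <- x
    }
    # de-mean each source per epoch
    for (i in seq_along(hyp$labels)) {
      idx <- (i - 1L) * ep_len + seq_len(ep_len)
      S[, idx] <- S[, idx] - rowMeans(S[, idx, drop = FALSE])
    }
    ev <- if (length(all_events)) do.call(rbind, all_events)
          else data.frame(source = character(), stage = character(),
                          type = character(), epoch = integer(),
                          sample = integer())
    attr(S, "events") <- ev
    attr(S, "fs") <- fs
    S
  })
}

#' Mix latent sources into observed channels
#'
#' Applies the instantaneous linear mixing model: observed = A %*% sources +
#' Gaussian sensor noise.
#'
#' @param latent_sources source x time matrix (e.g. from
#'   [synthesize_sources]).
#' @param mixing a [mixing_model]; its matrix must have as many columns as
#'   there are sources.
#' @param seed integer seed for the sensor noise.
#' @param fs sampling rate (taken from the source matrix attribute when
#'   present).
#' @return a [psg_recording] with the model's channel order.
#' @export
mix_channels <- function(latent_sources, mixing = default_mixing_model(),
                         seed = 1, fs = attr(latent_sources, "fs")) {
  stopifnot(inherits(mixing, "mixing_model"))
  if (ncol(mixing$mixing_matrix) != nrow(latent_sources))
    stopf("mixing matrix has %d columns but there are %d sources",
          ncol(mixing$mixing_matrix), nrow(latent_sources))
  if (is.null(fs)) stopf("sampling rate unknown; pass `fs`")
  X <- mixing$mixing_matrix %*% latent_sources
  if (mixing$noise_sd > 0)
    X <- X + with_seed(seed, matrix(stats::rnorm(length(X), sd = mixing$noise_sd),
                                    nrow = nrow(X)))
  psg_recording(X, fs = fs, channel_labels = mixing$channel_labels)
}

#' Generate a complete synthetic subject
#'
#' Draws a hypnogram, synthesizes latent sources, and mixes them into the
#' observed 4-channel montage (Fp1, Fp2, E1, E2). All randomness flows from
#' the single `seed`.
#'
#' @param subject_id character id.
#' @param n_epochs number of 30-s epochs (default 240, i.e. 2 h).
#' @param fs generation sampling rate (default 256 Hz so that the
#'   resample-to-128-Hz stage is exercised non-trivially).
#' @param configs stage spectral configurations.
#' @param mixing a [mixing_model].
#' @param transition_matrix hypnogram transition matrix.
#' @param seed integer master seed for this subject.
#' @return a `psg_subject` list: `subject_id`, `recording`
#'   ([psg_recording]), `hypnogram`, `latent_sources`, `mixing`, `seed`.
#' @export
make_synthetic_subject <- function(subject_id, n_epochs = 240, fs = 256,
                                   configs = default_stage_configs(),
                                   mixing = default_mixing_model(),
                                   transition_matrix = default_transitions(),
                                   seed = 1) {
  hyp <- make_hypnogram(n_epochs, transition_matrix, seed = seed)
  S <- synthesize_sources(hyp, fs = fs, configs = configs, seed = seed + 1L)
  rec <- mix_channels(S, mixing, seed = seed + 2L, fs = fs)
  structure(list(subject_id = as.character(subject_id), recording = rec,
                 hypnogram = hyp, latent_sources = S, mixing = mixing,
                 seed = seed),
            class = "psg_subject")
}

#' @export
print.psg_subject <- function(x, ...) {
  cat(sprintf("<psg_subject> '%s': %d epochs @ %g Hz, seed %d\n",
              x$subject_id, length(x$hypnogram$labels), x$recording$fs,
              x$seed))
  print(x$hypnogram)
  invisible(x)
}
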