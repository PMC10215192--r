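# Signal conditioning: notch, band-pass, resampling, epoch segmentation.
# All filters are applied zero-phase (forward-backward) with reflect padding,
# so stage boundaries are not shifted in time.

# Zero-phase filtering with reflection padding at both ends. Pad length is
# capped at n-1; 3 s of signal (or 1024 samples if fs unknown) is plenty for
# the filters used here.
filtfilt_reflect <- function(b, a, x, pad = min(length(x) - 1L, 3072L)) {
  n <- length(x)
  if (pad > 0) {
    head_ref <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    tail_ref <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xp <- c(head_ref, x, tail_ref)
  } else xp <- x
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y <- as.numeric(y)
  y[pad + seq_len(n)]
}

apply_channelwise <- function(rec, f) {
  out <- t(apply(rec$samples, 1L, f))
  psg_recording(out, fs = rec$fs, channel_labels = rec$channel_labels)
}

# RBJ biquad notch coefficients for centre f0 and quality factor Q.
notch_coefficients <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Power-line notch filter
#'
#' Removes 50 or 60 Hz line interference with a quality-factor-30 biquad
#' notch applied zero-phase: the passband stays within +/- 1 dB outside
#' `line_freq` +/- 2 Hz while the line frequency itself is attenuated by far
#' more than 20 dB.
#'
#' @param rec a [psg_recording].
#' @param line_freq line frequency in Hz, 50 or 60; must be below Nyquist.
#' @param q notch quality factor (centre frequency / -3 dB bandwidth of a
#'   single pass).
#' @return filtered [psg_recording], same shape.
#' @export
notch_filter <- function(rec, line_freq = 50, q = 30) {
  stopifnot(inherits(rec, "psg_recording"))
  if (line_freq >= rec$fs / 2)
    stopf("line frequency %g Hz is not below Nyquist (%g Hz)",
          line_freq, rec$fs / 2)
  co <- notch_coefficients(line_freq, rec$fs, q)
  apply_channelwise(rec, function(x) filtfilt_reflect(co$b, co$a, x))
}

#' Band-pass filter (0.3-35 Hz default)
#'
#' Zero-phase band-pass implemented as a cascade of a 2nd-order Butterworth
#' high-pass at `low` and a 7th-order Butterworth low-pass at `high`. The
#' cascade realization keeps the 1-30 Hz passband within +/- 1 dB and
#' attenuates DC and content above 45 Hz by more than 20 dB under zero-phase
#' application, and avoids the numerical fragility of a direct-form band-pass
#' with a 0.3 Hz edge.
#'
#' @param rec a [psg_recording].
#' @param low high-pass edge in Hz.
#' @param high low-pass edge in Hz.
#' @return filtered [psg_recording], same shape.
#' @export
bandpass_filter <- function(rec, low = 0.3, high = 35) {
  stopifnot(inherits(rec, "psg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stopf("invalid band [%g, %g] Hz for fs %g Hz (need 0 < low < high < fs/2)",
          low, high, rec$fs)
  hp <- signal::butter(2, low / (rec$fs / 2), type = "high")
  lp <- signal::butter(7, high / (rec$fs / 2), type = "low")
  apply_channelwise(rec, function(x) {
    filtfilt_reflect(lp$b, lp$a, filtfilt_reflect(hp$b, hp$a, x))
  })
}

#' Resample a recording to a lower rate
#'
#' Polyphase rational resampling: the rate ratio is reduced to lowest terms
#' p/q, the signal is zero-stuffed by p, convolved with a linear-phase
#' windowed-sinc anti-alias filter whose group delay is compensated exactly,
#' and decimated by q. Only downsampling (or the identity) is supported.
#'
#' @param rec a [psg_recording].
#' @param target_fs target sampling rate in Hz (default 128).
#' @return resampled [psg_recording] of length `round(n * target_fs / fs)`.
#' @export
resample_recording <- function(rec, target_fs = 128) {
  stopifnot(inherits(rec, "psg_recording"))
  if (target_fs > rec$fs)
    stopf("upsampling (%g -> %g Hz) is not supported", rec$fs, target_fs)
  if (target_fs == rec$fs) return(rec)
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  d <- gcd(round(target_fs * 1000), round(rec$fs * 1000))
  p <- round(target_fs * 1000) / d
  q <- round(rec$fs * 1000) / d
  out <- t(apply(rec$samples, 1L, resample_poly, p = p, q = q))
  psg_recording(out, fs = target_fs, channel_labels = rec$channel_labels)
}

# Linear convolution via FFT at a highly composite transform length (plain
# stats::convolve uses the exact output length, which can have large prime
# factors and make the FFT orders of magnitude slower on long recordings).
fft_convolve <- function(x, h) {
  L <- length(x) + length(h) - 1L
  N <- stats::nextn(L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(N - length(x))))
  H <- stats::fft(c(h, numeric(N - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(L)] / N
}

# Rational p/q resampling of one channel with a Hamming-windowed sinc FIR
# (10 sidelobes per polyphase branch), reflect padding, and exact delay
# compensation. Output sample k sits at time (k-1) * q / (p * fs_in), i.e.
# aligned with input sample 1.
resample_poly <- function(x, p, q) {
  n <- length(x)
  m <- max(p, q)
  half <- 10L * m                       # FIR half-length (upsampled rate)
  npad <- ceiling(half / p) + 1L        # reflect padding (input samples)
  npad <- min(npad, n - 1L)
  xp <- c(2 * x[1] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  up <- numeric(length(xp) * p)
  up[seq(1L, by = p, length.out = length(xp))] <- xp
  t <- (-half):half
  h <- ifelse(t == 0, 2 / (2 * m), sin(pi * t / m) / (pi * t))
  h <- h * (0.54 + 0.46 * cos(pi * t / half))      # Hamming window
  h <- p * h / sum(h)
  y_full <- fft_convolve(up, h)
  f_up <- y_full[(half + 1L):(half + length(up))]  # delay-compensated
  n_out <- round(n * p / q)
  f_up[npad * p + 1L + (seq_len(n_out) - 1L) * q]
}

#' Segment a recording into labelled 30-s epochs
#'
#' Cuts each channel into consecutive epochs of `epoch_seconds` and aligns
#' them with the hypnogram. A trailing partial epoch is dropped; when the
#' number of full epochs and the number of labels disagree, the shorter of
#' the two wins with a warning.
#'
#' @param rec a [psg_recording] (the staging pipeline expects 128 Hz).
#' @param hyp a [hypnogram].
#' @param subject_id identifier carried into the dataset.
#' @return an `epoched_dataset`: list with `epochs` (named list of L x P
#'   matrices, one per channel), `labels` (character), `fs`, `subject_id`.
#' @export
epoch_segment <- function(rec, hyp, subject_id = "") {
  stopifnot(inherits(rec, "psg_recording"), inherits(hyp, "hypnogram"))
  P <- hyp$epoch_seconds * rec$fs
  if (P != round(P)) stopf("epoch length is not a whole number of samples")
  P <- as.integer(P)
  n_full <- ncol(rec$samples) %/% P
  if (n_full < 1) stopf("recording shorter than one full epoch")
  L <- min(n_full, length(hyp$labels))
  if (n_full != length(hyp$labels))
    warnf("signal has %d full epochs but %d labels; using first %d",
          n_full, length(hyp$labels), L)
  epochs <- lapply(seq_len(nrow(rec$samples)), function(ch) {
    matrix(rec$samples[ch, seq_len(L * P)], nrow = L, ncol = P, byrow = TRUE)
  })
  names(epochs) <- rec$channel_labels
  structure(list(epochs = epochs, labels = hyp$labels[seq_len(L)],
                 fs = rec$fs, epoch_seconds = hyp$epoch_seconds,
                 subject_id = subject_id),
            class = "epoched_dataset")
}

#' @export
print.epoched_dataset <- function(x, ...) {
  cat(sprintf("<epoched_dataset> '%s': %d epochs x %d samples, %d channel(s) @ %g Hz\n",
              x$subject_id, length(x$labels), ncol(x$epochs[[1]]),
              length(x$epochs), x$fs))
  invisible(x)
}

#' Run the full conditioning chain on a recording
#'
#' Notch, 0.3-35 Hz band-pass, then resampling to 128 Hz — the conditioning
#' applied to every channel before source separation and staging.
#'
#' @inheritParams notch_filter
#' @inheritParams bandpass_filter
#' @param target_fs resampling target (Hz).
#' @return conditioned [psg_recording] at `target_fs`.
#' @export
preprocess_recording <- function(rec, line_freq = 50, low = 0.3, high = 35,
                                 target_fs = 128) {
  rec |>
    notch_filter(line_freq = line_freq) |>
    bandpass_filter(low = low, high = high) |>
    resample_recording(target_fs = target_fs)
}
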