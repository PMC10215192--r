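# Minimal European Data Format (EDF) writer/reader: 16-bit samples, 1-second
# data records, linear physical scaling per channel. Covers what the pipeline
# needs (continuous multichannel recordings with integer sampling rates);
# hypnograms travel as a plain-text sidecar, one stage label per line.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

fmt_phys <- function(v) {
  # physical min/max must fit 8 ASCII chars
  s <- formatC(signif(v, 6), format = "g", digits = 6)
  if (nchar(s) > 8) s <- formatC(v, format = "g", digits = 4)
  s
}

#' Write a recording (or synthetic subject) to an EDF file
#'
#' Samples are quantized to 16 bits with per-channel linear scaling; data
#' records are 1 s long, so the sampling rate must be a whole number. When a
#' `psg_subject` is given, its hypnogram is written beside the EDF as a
#' plain-text sidecar (same path with extension `.hyp`), one of
#' `W/N1/N2/N3/REM` per line.
#'
#' @param x a [psg_recording] or `psg_subject`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path) {
  hyp <- NULL
  if (inherits(x, "psg_subject")) {
    hyp <- x$hypnogram
    rec <- x$recording
    patient <- x$subject_id
  } else if (inherits(x, "psg_recording")) {
    rec <- x
    patient <- "X"
  } else stopf("`x` must be a psg_recording or psg_subject")
  fs <- rec$fs
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  fs <- as.integer(fs)
  n <- ncol(rec$samples)
  n_rec <- n %/% fs
  if (n_rec < 1) stopf("recording shorter than one 1-s data record")
  if (n_rec * fs != n)
    warnf("dropping %d trailing samples (partial EDF record)", n - n_rec * fs)
  ns <- nrow(rec$samples)

  dig_min <- -32768; dig_max <- 32767
  phys_max <- apply(rec$samples, 1L, function(v) max(abs(v), 1e-6))
  phys_max <- vapply(phys_max, function(v) as.numeric(fmt_phys(v * 1.0001)),
                     numeric(1))
  phys_min <- -phys_max

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(patient, 80),
    edf_field("synthetic PSG", 80),
    edf_field("01.01.24", 8),
    edf_field("00.00.00", 8),
    edf_field(256 * (1 + ns), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field("1", 8),
    edf_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(vapply(rec$channel_labels, edf_field, "", width = 16), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(phys_min, function(v) edf_field(fmt_phys(v), 8), ""), collapse = ""),
    paste(vapply(phys_max, function(v) edf_field(fmt_phys(v), 8), ""), collapse = ""),
    paste(rep(edf_field(dig_min, 8), ns), collapse = ""),
    paste(rep(edf_field(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(fs, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = ""))
  writeChar(sig_hdr, con, eos = NULL)

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round(sweep(sweep(rec$samples[, seq_len(n_rec * fs), drop = FALSE],
                           1L, phys_min, "-"), 1L, scale, "/")) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  # interleave: per record, per signal, fs samples
  arr <- array(t(dig), dim = c(fs, n_rec, ns))       # sample, record, signal
  out <- as.integer(aperm(arr, c(1, 3, 2)))          # sample, signal, record
  writeBin(out, con, size = 2L, endian = "little")

  if (!is.null(hyp))
    writeLines(hyp$labels, sub("\\.edf$", ".hyp", path, ignore.case = TRUE))
  invisible(path)
}

#' Read an EDF file written by this package (or any 16-bit continuous EDF)
#'
#' @param path EDF file path.
#' @param channels optional character vector of required channel labels;
#'   an error is raised if any is missing.
#' @return a [psg_recording].
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stopf("EDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec))
    stopf("not a readable EDF header: %s", path)
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1)
    stopf("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * sum(spr))
    stopf("EDF data truncated: %s", path)
  arr <- array(raw, dim = c(spr[1], ns, n_rec))
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  X <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  for (i in seq_len(ns))
    X[i, ] <- as.numeric(arr[, i, ]) * scale[i] +
      (phys_min[i] - dig_min[i] * scale[i])
  if (!is.null(channels)) {
    miss <- setdiff(channels, labels)
    if (length(miss))
      stopf("EDF file %s is missing channel(s): %s", path,
            paste(miss, collapse = ", "))
  }
  psg_recording(X, fs = fs, channel_labels = labels)
}

#' Read a plain-text hypnogram sidecar
#'
#' @param path text file with one stage label (`W/N1/N2/N3/REM`) per line.
#' @param epoch_seconds epoch length.
#' @return a [hypnogram].
#' @export
read_hypnogram <- function(path, epoch_seconds = 30) {
  if (!file.exists(path)) stopf("hypnogram file not found: %s", path)
  hypnogram(readLines(path), epoch_seconds = epoch_seconds)
}
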