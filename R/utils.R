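#' @keywords internal
"_PACKAGE"

# Five-stage AASM vocabulary used throughout; order fixes the class index.
STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Multichannel recording container
#'
#' A lightweight container for a multichannel signal: a channels x time
#' numeric matrix in microvolts, a sampling rate in Hz, and ordered channel
#' labels.
#'
#' @param samples numeric matrix, channels x time (microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per row of `samples`.
#' @return an object of class `psg_recording`.
#' @export
psg_recording <- function(samples, fs, channel_labels) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stopf("`samples` must be a numeric channels x time matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("`fs` must be a single positive number")
  if (length(channel_labels) != nrow(samples))
    stopf("%d channel labels supplied for %d channels",
          length(channel_labels), nrow(samples))
  if (any(!is.finite(samples)))
    stopf("`samples` contains NaN/Inf values")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels)),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of a recording as a numeric vector
#' @param x a `psg_recording`.
#' @param channel channel label or index.
#' @return numeric vector of samples.
#' @export
channel <- function(x, channel) {
  stopifnot(inherits(x, "psg_recording"))
  if (is.character(channel) && !channel %in% x$channel_labels)
    stopf("channel '%s' not found (have: %s)", channel,
          paste(x$channel_labels, collapse = ", "))
  as.numeric(x$samples[channel, ])
}

#' Per-epoch hypnogram
#'
#' Stage labels scored per fixed-length epoch, aligned to a recording.
#'
#' @param labels character vector of stage labels in `W, N1, N2, N3, REM`.
#' @param epoch_seconds epoch length in seconds (default 30, the AASM scoring
#'   convention).
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_seconds = 30) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), STAGES)
  if (length(bad))
    stopf("unknown stage label(s): %s", paste(bad, collapse = ", "))
  structure(list(labels = labels, epoch_seconds = epoch_seconds),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = STAGES))
  cat(sprintf("<hypnogram> %d epochs x %g s\n", length(x$labels),
              x$epoch_seconds))
  print(tab)
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)
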