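# Correlation-calibrated construction of EEG-coupled EOG signals:
# coupledEOG = rawEOG + a * cleanEEG, with the superposition factor a solved
# in closed form so that corr(coupledEOG, cleanEEG) hits a prescribed target.

check_pair <- function(raw_eog, clean_eeg, min_len = 2) {
  if (length(raw_eog) != length(clean_eeg))
    stopf("signals differ in length (%d vs %d)",
          length(raw_eog), length(clean_eeg))
  if (length(raw_eog) < min_len)
    stopf("signals must have at least %d samples", min_len)
}

#' Solve the superposition factor for a target correlation
#'
#' Finds `a` such that `corr(raw_eog + a * clean_eeg, clean_eeg)` equals
#' `target_rho`, by solving the quadratic obtained from the Pearson
#' correlation definition:
#' `v^2 (1 - rho^2) a^2 + 2 c v (1 - rho^2) a + (c^2 - rho^2 u v) = 0`
#' with `c = cov(raw, clean)`, `u = var(raw)`, `v = var(clean)`. Among the
#' real roots whose achieved correlation matches the target (squaring can
#' introduce a sign-spurious root), the one with smallest `|a|` is returned —
#' the minimal perturbation of the raw signal. Negative `a` is permitted; it
#' removes EEG content and realizes the target-0 "clean EOG" case as
#' `a = -cov(raw, clean) / var(clean)`.
#'
#' @param raw_eog,clean_eeg equal-length (>= 100), non-constant signals.
#' @param target_rho target correlation, `|target_rho| < 1`.
#' @return scalar `a` (dimensionless).
#' @export
solve_superposition_factor <- function(raw_eog, clean_eeg, target_rho) {
  check_pair(raw_eog, clean_eeg, min_len = 100)
  if (abs(target_rho) >= 1)
    stopf("|target_rho| must be < 1 (got %g)", target_rho)
  v <- stats::var(clean_eeg)
  u <- stats::var(raw_eog)
  if (v < .Machine$double.eps) stopf("clean_eeg is constant")
  if (u < .Machine$double.eps) stopf("raw_eog is constant")
  cc <- stats::cov(raw_eog, clean_eeg)
  rho <- target_rho
  A <- v^2 * (1 - rho^2)
  B <- 2 * cc * v * (1 - rho^2)
  C <- cc^2 - rho^2 * u * v
  disc <- B^2 - 4 * A * C
  # the target-0 case has a double root: disc is exactly 0 analytically and
  # may round to a tiny negative number
  if (disc < 0 && disc > -1e-9 * max(B^2, abs(4 * A * C))) disc <- 0
  if (disc < 0) stopf("no real superposition factor reaches target %g", rho)
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  achieved <- vapply(roots, function(a)
    stats::cor(raw_eog + a * clean_eeg, clean_eeg), numeric(1))
  ok <- which(abs(achieved - rho) <= 1e-9)
  if (!length(ok)) {
    # fall back to the closest root (numerical round-off on huge signals)
    ok <- which.min(abs(achieved - rho))
    if (abs(achieved[ok] - rho) > 1e-6)
      stopf("calibration failed: best achievable correlation %.8f for target %g",
            achieved[ok], rho)
  }
  roots[ok][which.min(abs(roots[ok]))]
}

#' Form a coupled EOG signal
#'
#' The exact elementwise linear combination
#' `coupledEOG = rawEOG + a * cleanEEG`.
#'
#' @param raw_eog,clean_eeg equal-length signals (microvolts).
#' @param a superposition factor.
#' @return coupled signal (microvolts).
#' @export
make_coupled_eog <- function(raw_eog, clean_eeg, a) {
  check_pair(raw_eog, clean_eeg)
  raw_eog + a * clean_eeg
}

#' Pearson correlation between clean EEG and a coupled EOG
#'
#' Computed over the whole recording (all concatenated samples), matching a
#' single per-subject content value.
#'
#' @param clean_eeg,coupled equal-length (>= 2), non-constant signals.
#' @return correlation in `[-1, 1]`.
#' @export
measure_correlation <- function(clean_eeg, coupled) {
  check_pair(clean_eeg, coupled)
  if (stats::var(clean_eeg) == 0 || stats::var(coupled) == 0)
    stopf("correlation undefined for a constant signal")
  stats::cor(clean_eeg, coupled)
}

#' Mean absolute error between two signals
#'
#' @param raw_eog,coupled equal-length signals (microvolts).
#' @return mean of absolute sample differences (microvolts).
#' @export
mae <- function(raw_eog, coupled) {
  check_pair(raw_eog, coupled, min_len = 1)
  mean(abs(coupled - raw_eog))
}

#' Build the full coupled-EOG set for a target grid
#'
#' For each target correlation level, calibrates the superposition factor,
#' forms the coupled signal, and records the achieved correlation and the
#' MAE against the raw EOG. The correlation between the raw EOG and the
#' clean EEG is reported as the raw-content baseline.
#'
#' @param raw_eog,clean_eeg equal-length signals (microvolts).
#' @param targets target correlation levels (default the study grid
#'   0.0, 0.1, 0.2, 0.3, 0.5).
#' @param keep_signals keep the coupled signals in the result (set FALSE to
#'   save memory when only the summary is needed).
#' @return a `coupled_eog_set`: `entries` data frame (target_rho, a,
#'   achieved_rho, mae_vs_raw), `signals` (named list of coupled signals,
#'   when kept), `raw_clean_corr`.
#' @export
build_coupled_set <- function(raw_eog, clean_eeg,
                              targets = c(0.0, 0.1, 0.2, 0.3, 0.5),
                              keep_signals = TRUE) {
  check_pair(raw_eog, clean_eeg, min_len = 100)
  entries <- data.frame(target_rho = targets, a = NA_real_,
                        achieved_rho = NA_real_, mae_vs_raw = NA_real_)
  signals <- if (keep_signals) vector("list", length(targets)) else NULL
  for (i in seq_along(targets)) {
    a <- solve_superposition_factor(raw_eog, clean_eeg, targets[i])
    coupled <- make_coupled_eog(raw_eog, clean_eeg, a)
    entries$a[i] <- a
    entries$achieved_rho[i] <- measure_correlation(clean_eeg, coupled)
    entries$mae_vs_raw[i] <- mae(raw_eog, coupled)
    if (keep_signals) signals[[i]] <- coupled
  }
  if (keep_signals) names(signals) <- sprintf("rho_%.1f", targets)
  structure(list(entries = entries, signals = signals,
                 raw_clean_corr = stats::cor(raw_eog, clean_eeg)),
            class = "coupled_eog_set")
}

#' @export
print.coupled_eog_set <- function(x, digits = 4, ...) {
  cat(sprintf("<coupled_eog_set> raw EOG ~ clean EEG correlation: %.4f\n",
              x$raw_clean_corr))
  print(format(x$entries, digits = digits), row.names = FALSE)
  invisible(x)
}
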