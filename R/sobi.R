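# Second-order blind identification (SOBI): normalize -> whiten -> lagged
# covariances -> joint approximate diagonalization by Givens rotations ->
# source reconstruction, plus correlation-based ocular component removal.

#' Normalize channels to zero mean and unit variance
#'
#' @param X channels x time numeric matrix (at least 2 channels and 10x as
#'   many samples as channels).
#' @return matrix of the same shape; attributes `center` and `scale` hold the
#'   per-channel mean and standard deviation.
#' @export
sobi_normalize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("need at least 2 channels")
  if (ncol(X) < 10 * nrow(X)) stopf("need at least 10x channels samples")
  ctr <- rowMeans(X)
  Xc <- X - ctr
  sds <- sqrt(rowSums(Xc^2) / (ncol(X) - 1))
  const <- which(sds < .Machine$double.eps^0.5 * (abs(ctr) + 1))
  if (length(const)) {
    nm <- rownames(X)[const[1]]
    stopf("channel %s is constant and cannot be normalized",
          if (is.null(nm)) as.character(const[1]) else sprintf("'%s'", nm))
  }
  X0 <- Xc / sds
  attr(X0, "center") <- ctr
  attr(X0, "scale") <- sds
  X0
}

#' Whiten normalized data
#'
#' Symmetric (inverse-square-root) whitening: `M = C^{-1/2}` for the sample
#' covariance `C` of `X0`, so that `M` is the identity when `X0` is already
#' white.
#'
#' @param X0 normalized channels x time matrix.
#' @return list with `Z = M %*% X0` (sample covariance = identity) and the
#'   whitening matrix `M`.
#' @export
sobi_whiten <- function(X0) {
  X0 <- as.matrix(X0)
  Xc <- X0 - rowMeans(X0)
  C <- tcrossprod(Xc) / (ncol(X0) - 1)
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values))
    stopf(paste("covariance is (near-)rank-deficient; remove a redundant",
                "channel before separation"))
  M <- eg$vectors %*% diag(1 / sqrt(eg$values), nrow(C)) %*% t(eg$vectors)
  list(Z = M %*% X0, M = M)
}

#' Time-lagged covariance matrices
#'
#' Computes `R(tau) = E[Z(t + tau) Z(t)']` for each requested lag and
#' symmetrizes each as `(R + R') / 2`.
#'
#' @param Z whitened channels x time matrix.
#' @param lags non-negative integer sample lags (lag 0 gives the ordinary
#'   covariance); max lag must be below a tenth of the sample count.
#' @return named list of symmetric matrices, one per lag.
#' @export
delayed_covariances <- function(Z, lags) {
  Z <- as.matrix(Z)
  lags <- as.integer(lags)
  if (any(lags < 0)) stopf("lags must be non-negative integers")
  if (max(lags) >= ncol(Z) / 10)
    stopf("max lag %d too large for %d samples", max(lags), ncol(Z))
  n <- ncol(Z)
  out <- lapply(lags, function(tau) {
    R <- tcrossprod(Z[, (1 + tau):n, drop = FALSE],
                    Z[, 1:(n - tau), drop = FALSE]) / (n - tau)
    (R + t(R)) / 2
  })
  names(out) <- paste0("lag", lags)
  out
}

off_diag_mass <- function(mats) {
  sum(vapply(mats, function(R) sum(R^2) - sum(diag(R)^2), numeric(1)))
}

#' Joint approximate diagonalization by Givens rotations
#'
#' Finds an orthogonal matrix `U` that simultaneously (approximately)
#' diagonalizes a set of symmetric matrices, by Jacobi-style sweeps of Givens
#' rotations, each rotation chosen to maximally reduce the summed squared
#' off-diagonal mass of the rotated set (Cardoso-Souloumiac angle).
#'
#' @param matrices list of equal-size symmetric matrices.
#' @param tol convergence tolerance on the rotation angle (radians): a sweep
#'   in which every rotation has `|sin| < tol` stops the iteration.
#' @param max_sweeps maximum number of full sweeps.
#' @return list with the orthogonal `U`, `sweeps` used, `off_diag` (summed
#'   squared off-diagonal mass after each sweep, monotone non-increasing),
#'   and `converged`.
#' @export
joint_diagonalize <- function(matrices, tol = 1e-8, max_sweeps = 200) {
  if (!length(matrices)) stopf("need at least one matrix")
  m <- nrow(matrices[[1]])
  for (R in matrices) {
    if (!is.matrix(R) || nrow(R) != m || ncol(R) != m)
      stopf("all matrices must be square and of equal size")
    if (max(abs(R - t(R))) > 1e-8 * max(1, max(abs(R))))
      stopf("matrices must be symmetric")
  }
  A <- lapply(matrices, function(R) (R + t(R)) / 2)
  K <- length(A)
  U <- diag(m)
  history <- numeric(0)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    max_s <- 0
    for (p in 1:(m - 1)) for (q in (p + 1):m) {
      # rotation angle maximizing joint diagonality over the matrix set
      # (for a single matrix this reduces to the classical Jacobi angle
      # tan(2 theta) = 2 A[p,q] / (A[p,p] - A[q,q]))
      h1 <- vapply(A, function(R) R[p, p] - R[q, q], numeric(1))
      h2 <- vapply(A, function(R) 2 * R[p, q], numeric(1))
      ton <- sum(h1 * h1) - sum(h2 * h2)
      toff <- 2 * sum(h1 * h2)
      theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
      c_ <- cos(theta); s_ <- sin(theta)
      if (abs(s_) > max_s) max_s <- abs(s_)
      if (abs(s_) < tol) next
      G <- diag(m); G[p, p] <- c_; G[q, q] <- c_
      G[p, q] <- -s_; G[q, p] <- s_
      A <- lapply(A, function(R) crossprod(G, R %*% G))
      U <- U %*% G
    }
    history <- c(history, off_diag_mass(A))
    if (max_s < tol) { converged <- TRUE; break }
  }
  list(U = U, sweeps = length(history), off_diag = history,
       converged = converged)
}

#' Second-order blind identification
#'
#' Runs the full SOBI chain on a channels x time matrix or recording:
#' per-channel normalization, symmetric whitening, time-lagged covariance
#' estimation, joint approximate diagonalization, and source reconstruction
#' `S = U' Z`. Components are ordered by descending back-projected variance
#' and sign-fixed so that each column of the estimated mixing matrix has a
#' positive largest-magnitude loading.
#'
#' @param x a [psg_recording] or channels x time numeric matrix.
#' @param lags positive sample lags for the covariance set (default 1:100;
#'   at 128 Hz this spans roughly 0.01-0.8 s of autocorrelation structure).
#' @param tol,max_sweeps passed to [joint_diagonalize].
#' @return an object of class `sobi`: `X0` (normalized data), `M` (whitening
#'   matrix), `Z` (whitened data), `lags`, `R_tau` (lagged covariances), `U`
#'   (orthogonal diagonalizer), `S` (estimated sources),
#'   `mixing_estimate` (map from sources back to normalized channels),
#'   `center`/`scale` (normalization parameters), `channel_labels`,
#'   `contrast` (energy of the lagged covariances relative to the sampling
#'   noise floor) and `low_contrast` (TRUE when the lagged covariances carry
#'   too little structure for reliable separation, e.g. temporally white
#'   sources — second-order identifiability requires distinct lagged
#'   spectra).
#' @export
sobi <- function(x, lags = 1:100, tol = 1e-8, max_sweeps = 200) {
  if (inherits(x, "psg_recording")) {
    X <- x$samples
    labels <- x$channel_labels
  } else {
    X <- as.matrix(x)
    labels <- rownames(X)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(X)))
  }
  X0 <- sobi_normalize(X)
  wh <- sobi_whiten(X0)
  R_tau <- delayed_covariances(wh$Z, lags)
  jd <- joint_diagonalize(R_tau, tol = tol, max_sweeps = max_sweeps)
  U <- jd$U
  S <- crossprod(U, wh$Z)
  A_est <- solve(wh$M) %*% U   # X0 = A_est %*% S
  # order components by back-projected variance, fix signs
  v <- colSums(A_est^2) * apply(S, 1L, stats::var)
  ord <- order(v, decreasing = TRUE)
  U <- U[, ord, drop = FALSE]
  S <- S[ord, , drop = FALSE]
  A_est <- A_est[, ord, drop = FALSE]
  for (j in seq_len(ncol(A_est))) {
    k <- which.max(abs(A_est[, j]))
    if (A_est[k, j] < 0) {
      A_est[, j] <- -A_est[, j]; U[, j] <- -U[, j]; S[j, ] <- -S[j, ]
    }
  }
  rownames(S) <- paste0("IC", seq_len(nrow(S)))
  # diagonalization contrast: energy of the lagged covariances relative to
  # the sampling-noise floor (each entry of R(tau) has variance ~ 1/N for
  # temporally white data, so E||R||_F^2 ~ m^2/N under the null)
  m_ch <- nrow(wh$Z)
  null_level <- m_ch^2 / ncol(wh$Z)
  contrast <- mean(vapply(R_tau, function(R) sum(R^2), numeric(1))) /
    null_level
  low <- contrast < 10
  if (low)
    warnf(paste("low diagonalization contrast (%.1f x noise floor): sources",
                "have little lagged-covariance structure; separation may be",
                "unreliable"), contrast)
  structure(list(X0 = X0, M = wh$M, Z = wh$Z, lags = as.integer(lags),
                 R_tau = R_tau, U = U, S = S, mixing_estimate = A_est,
                 center = attr(X0, "center"), scale = attr(X0, "scale"),
                 channel_labels = labels, sweeps = jd$sweeps,
                 off_diag = jd$off_diag, converged = jd$converged,
                 contrast = contrast, low_contrast = low),
            class = "sobi")
}

#' @export
print.sobi <- function(x, ...) {
  cat(sprintf("<sobi> %d components from channels: %s\n", nrow(x$S),
              paste(x$channel_labels, collapse = ", ")))
  cat(sprintf("  lags 1..%d (%d matrices), %d sweep(s), %s\n",
              max(x$lags), length(x$lags), x$sweeps,
              if (x$converged) "converged" else "max sweeps reached"))
  cat(sprintf("  diagonalization contrast: %.1f x noise floor%s\n", x$contrast,
              if (x$low_contrast) " (LOW)" else ""))
  invisible(x)
}

#' Remove ocular components and reconstruct clean EEG
#'
#' Scores every separated component by its maximum absolute correlation with
#' the reference EOG channels, zeroes components at or above `threshold`, and
#' back-projects the remaining components onto the EEG channels.
#'
#' @param separation a [sobi] fit.
#' @param reference_eog reference EOG signals time-aligned with the separated
#'   data: a [psg_recording] or channels x time matrix.
#' @param threshold absolute-correlation threshold in `[0, 1]` at or above
#'   which a component is considered ocular (default 0.7).
#' @param eeg_channels labels of the channels to reconstruct.
#' @return a [psg_recording] of the cleaned EEG channels (original microvolt
#'   scale restored); attribute `selection` holds the per-component scores,
#'   the removed index set, and the threshold.
#' @param fs sampling rate for the output recording.
#' @export
remove_eog_components <- function(separation, reference_eog, threshold = 0.7,
                                  eeg_channels = c("Fp1", "Fp2"), fs = 128) {
  stopifnot(inherits(separation, "sobi"))
  R <- if (inherits(reference_eog, "psg_recording")) reference_eog$samples
       else if (is.vector(reference_eog)) matrix(reference_eog, nrow = 1)
       else as.matrix(reference_eog)
  if (ncol(R) != ncol(separation$S))
    stopf("reference EOG length %d does not match separated data length %d",
          ncol(R), ncol(separation$S))
  scores <- abs(stats::cor(t(separation$S), t(R)))
  max_score <- apply(scores, 1L, max)
  removed <- which(max_score >= threshold)
  if (length(removed) == nrow(separation$S))
    stopf(paste("all %d components correlate with the EOG reference at or",
                "above %.2f; threshold too low"),
          length(removed), threshold)
  eeg_idx <- match(eeg_channels, separation$channel_labels)
  if (anyNA(eeg_idx))
    stopf("EEG channel(s) not in separation: %s",
          paste(eeg_channels[is.na(eeg_idx)], collapse = ", "))
  keep <- setdiff(seq_len(nrow(separation$S)), removed)
  X0_clean <- if (length(keep))
    separation$mixing_estimate[eeg_idx, keep, drop = FALSE] %*%
      separation$S[keep, , drop = FALSE]
  else matrix(0, length(eeg_idx), ncol(separation$S))
  # restore original scale and offset
  X_clean <- X0_clean * separation$scale[eeg_idx] +
    separation$center[eeg_idx]
  out <- psg_recording(X_clean, fs = fs, channel_labels = eeg_channels)
  attr(out, "selection") <- list(component_scores = scores,
                                 removed = removed, threshold = threshold)
  out
}
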