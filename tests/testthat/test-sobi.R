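test_that("normalization gives zero mean and unit variance per channel", {
  X <- rbind(c(1, 2, 3), c(2, 4, 9))
  X <- cbind(X, X, X, X, X, X, X)           # >= 10x channels samples
  X0 <- sobi_normalize(X)
  expect_equal(rowMeans(X0), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(X0, 1, sd), c(1, 1), tolerance = 1e-12)

  # idempotence on standardized input
  expect_equal(unname(sobi_normalize(X0)), unname(X0[, ]), tolerance = 1e-12,
               ignore_attr = TRUE)

  # constant channel error names the channel
  Xc <- rbind(first = rnorm(50), flat = rep(2, 50))
  expect_error(sobi_normalize(Xc), "flat")
})

test_that("symmetric whitening produces identity covariance", {
  set.seed(1)
  # white input: M is the identity
  Xw <- matrix(rnorm(2 * 50000), 2)
  Xw <- sobi_normalize(Xw)
  C <- tcrossprod(Xw - rowMeans(Xw)) / (ncol(Xw) - 1)
  e <- eigen(C, symmetric = TRUE)
  Xw_exact <- (e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)) %*% Xw
  wh0 <- sobi_whiten(Xw_exact)
  expect_lt(max(abs(wh0$M - diag(2))), 1e-8)

  # correlated Gaussian pair
  z <- matrix(rnorm(2 * 20000), 2)
  X <- rbind(z[1, ], 0.8 * z[1, ] + sqrt(1 - 0.64) * z[2, ])
  wh <- sobi_whiten(X)
  covZ <- tcrossprod(wh$Z - rowMeans(wh$Z)) / (ncol(X) - 1)
  expect_lt(max(abs(covZ - diag(2))), 1e-6)

  # definition: M C M' = I
  CX <- tcrossprod(X - rowMeans(X)) / (ncol(X) - 1)
  expect_lt(max(abs(wh$M %*% CX %*% t(wh$M) - diag(2))), 1e-8)

  # rank-deficient input suggests channel removal
  Xr <- rbind(z[1, ], 2 * z[1, ])
  expect_error(sobi_whiten(Xr), "remove")
})

test_that("lagged covariances behave as theory predicts", {
  set.seed(2)
  N <- 40000
  Zw <- matrix(rnorm(2 * N), 2)
  R5 <- delayed_covariances(Zw, 5)[[1]]
  expect_lt(max(abs(R5)), 3 / sqrt(N))

  # lag 0 on whitened data is the identity
  wh <- sobi_whiten(Zw)
  R0 <- delayed_covariances(wh$Z, 0)[[1]]
  expect_lt(max(abs(R0 - diag(2))), 1e-3)

  # AR(1) with coefficient 0.9: lag-1 autocovariance / variance = 0.9
  x1 <- as.numeric(arima.sim(list(ar = 0.9), N))
  x2 <- as.numeric(arima.sim(list(ar = 0.9), N))
  Z <- rbind(x1 / sd(x1), x2 / sd(x2))
  R1 <- delayed_covariances(Z, 1)[[1]]
  expect_equal(diag(R1), c(0.9, 0.9), tolerance = 0.05)

  expect_error(delayed_covariances(Zw, N / 2), "too large")
})

test_that("joint diagonalization recovers a planted orthogonal basis", {
  set.seed(3)
  # already diagonal: U is a signed permutation, residual ~ 0
  mats <- list(diag(c(3, 1, 2)), diag(c(1, 5, 0.5)))
  jd <- joint_diagonalize(mats)
  P <- abs(jd$U)
  expect_true(all(colSums(P > 0.99) == 1) && all(rowSums(P > 0.99) == 1))
  rot <- lapply(mats, function(R) crossprod(jd$U, R %*% jd$U))
  expect_lt(sum(vapply(rot, function(R) sum(R^2) - sum(diag(R)^2),
                       numeric(1))), 1e-12)

  # construct-and-verify: Q D_k Q' for random orthogonal Q
  m <- 4
  Q <- qr.Q(qr(matrix(rnorm(m * m), m)))
  mats2 <- lapply(1:6, function(k) {
    D <- diag(runif(m, 0.1, 2) * sample(c(-1, 1), m, TRUE))
    Q %*% D %*% t(Q)
  })
  jd2 <- joint_diagonalize(mats2)
  M <- abs(crossprod(jd2$U, Q))   # should be a permutation matrix
  expect_true(all(apply(M, 1, max) > 1 - 1e-6))
  rot2 <- lapply(mats2, function(R) crossprod(jd2$U, R %*% jd2$U))
  expect_lt(sum(vapply(rot2, function(R) sum(R^2) - sum(diag(R)^2),
                       numeric(1))), 1e-8)

  # single matrix: diagonal equals its eigenvalues
  A <- crossprod(matrix(rnorm(25), 5))
  jd3 <- joint_diagonalize(list(A))
  d <- sort(diag(crossprod(jd3$U, A %*% jd3$U)))
  expect_equal(d, sort(eigen(A)$values), tolerance = 1e-8)

  # off-diagonal objective is monotone non-increasing over sweeps
  expect_true(all(diff(jd2$off_diag) <= 1e-12))

  expect_error(joint_diagonalize(list(matrix(rnorm(16), 4))), "symmetric")
})

test_that("sobi separates temporally structured sources", {
  set.seed(4)
  N <- 20000
  s1 <- as.numeric(arima.sim(list(ar = c(0.7, -0.3)), N))
  s2 <- as.numeric(arima.sim(list(ar = c(-0.4, 0.5)), N))
  S_true <- rbind(s1, s2)
  A <- matrix(c(1.2, -0.4, 0.7, 0.9), 2)
  X <- A %*% S_true
  fit <- sobi(X, lags = 1:20)
  expect_true(all(matched_source_correlations(fit$S, S_true) > 0.95))
  expect_false(fit$low_contrast)

  # identity mixing of uncorrelated colored sources: near-perfect recovery
  fit2 <- sobi(S_true, lags = 1:20)
  expect_true(all(matched_source_correlations(fit2$S, S_true) > 0.99))

  # i.i.d. Gaussian sources: completes but flags low contrast
  Xg <- matrix(rnorm(2 * N), 2)
  expect_warning(fitg <- sobi(Xg, lags = 1:20), "low diagonalization contrast")
  expect_true(fitg$low_contrast)

  # invariants: U orthogonal, cov(Z) = I, S = U'Z, round-trip reconstruction
  expect_lt(max(abs(crossprod(fit$U) - diag(2))), 1e-8)
  covZ <- tcrossprod(fit$Z - rowMeans(fit$Z)) / (N - 1)
  expect_lt(max(abs(covZ - diag(2))), 1e-6)
  expect_equal(unname(fit$S), crossprod(fit$U, fit$Z), tolerance = 1e-12)
  X0_hat <- fit$mixing_estimate %*% fit$S
  expect_lt(norm(X0_hat - fit$X0, "F") / norm(fit$X0, "F"), 1e-6)
})

test_that("channel permutation permutes recovered sources up to ordering", {
  set.seed(5)
  N <- 10000
  S_true <- rbind(as.numeric(arima.sim(list(ar = 0.9), N)),
                  as.numeric(arima.sim(list(ar = -0.6), N)),
                  as.numeric(arima.sim(list(ar = c(0.2, 0.6)), N)))
  A <- matrix(rnorm(9), 3) + diag(3)
  X <- A %*% S_true
  f1 <- sobi(X, lags = 1:20)
  f2 <- sobi(X[c(2, 3, 1), ], lags = 1:20)
  cm <- abs(stats::cor(t(f1$S), t(f2$S)))
  expect_true(all(apply(cm, 1, max) > 0.999))  # same sources, maybe reordered
})

test_that("ocular components are identified and removed", {
  pipe <- fixture_pipeline(101, n_epochs = 30)
  src <- pipe$sources128$samples
  clean <- pipe$clean
  expect_lt(abs(cor(clean$samples["Fp1", ], src["EOG_left", ])), 0.1)
  expect_gt(abs(cor(clean$samples["Fp1", ], src["EEG_left", ])), 0.9)
  expect_lt(abs(cor(clean$samples["Fp2", ], src["EOG_right", ])), 0.1)
  expect_gt(abs(cor(clean$samples["Fp2", ], src["EEG_right", ])), 0.9)

  # threshold above 1: nothing removed, back-projection returns the input
  sep <- pipe$sep
  ref <- pipe$rec$samples[c("E1", "E2"), ]
  full <- remove_eog_components(sep, ref, threshold = 1.01, fs = 128)
  expect_equal(full$samples["Fp1", ], pipe$rec$samples["Fp1", ],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_length(attr(full, "selection")$removed, 0)

  # threshold too low: every component flagged
  expect_error(remove_eog_components(sep, sep$S, threshold = 0, fs = 128),
               "threshold too low")
})
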