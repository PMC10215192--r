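# Independent oracle for the superposition factor: dense grid search over a.
grid_search_a <- function(raw, clean, target, width = 5, n = 200001) {
  a_grid <- seq(-width, width, length.out = n)
  ach <- vapply(a_grid, function(a) cor(raw + a * clean, clean), numeric(1))
  a_grid[which.min(abs(ach - target))]
}

test_that("superposition factor solves the correlation calibration exactly", {
  set.seed(10)
  n <- 2000
  clean <- as.numeric(arima.sim(list(ar = 0.8), n))
  raw <- as.numeric(arima.sim(list(ar = 0.95), n)) + 0.4 * clean

  # target equal to the current correlation: a = 0
  rho0 <- cor(raw, clean)
  expect_equal(solve_superposition_factor(raw, clean, rho0), 0,
               tolerance = 1e-9)

  # target 0: closed form -cov/var, verified against grid search
  a0 <- solve_superposition_factor(raw, clean, 0)
  expect_equal(a0, -cov(raw, clean) / var(clean), tolerance = 1e-12)
  expect_lt(abs(cor(raw + a0 * clean, clean)), 1e-9)
  expect_equal(a0, grid_search_a(raw, clean, 0), tolerance = 1e-4)

  # orthogonal signals: analytic solution a = rho*s_raw/(s_clean*sqrt(1-rho^2))
  raw_perp <- raw - clean * (cov(raw, clean) / var(clean))
  a3 <- solve_superposition_factor(raw_perp, clean, 0.3)
  a3_analytic <- 0.3 * sd(raw_perp) / (sd(clean) * sqrt(1 - 0.09))
  expect_equal(a3, a3_analytic, tolerance = 1e-6)
  expect_equal(cor(raw_perp + a3 * clean, clean), 0.3, tolerance = 1e-9)
  expect_equal(a3, grid_search_a(raw_perp, clean, 0.3), tolerance = 1e-4)

  expect_error(solve_superposition_factor(raw, clean, 1), "< 1")
  expect_error(solve_superposition_factor(raw, rep(1, n), 0.3), "constant")
})

test_that("calibration is exact over random pairs and monotone in a", {
  set.seed(11)
  for (trial in seq_len(1000)) {
    n <- 300
    clean <- rnorm(n)
    raw <- rnorm(n) + runif(1, -0.5, 0.5) * clean
    target <- runif(1, 0, 0.9)
    a <- solve_superposition_factor(raw, clean, target)
    expect_lt(abs(cor(raw + a * clean, clean) - target), 1e-6)
  }
  # achieved correlation strictly increasing in a near the returned root
  clean <- rnorm(500); raw <- rnorm(500)
  a <- solve_superposition_factor(raw, clean, 0.4)
  eps <- 1e-4
  lo <- cor(raw + (a - eps) * clean, clean)
  hi <- cor(raw + (a + eps) * clean, clean)
  expect_gt(hi, lo)
})

test_that("coupled signal construction is the exact linear combination", {
  expect_identical(make_coupled_eog(c(1, 2), c(1, -1), 0), c(1, 2))
  expect_equal(make_coupled_eog(c(1, 2), c(1, -1), 0.5), c(1.5, 1.5))
  # additivity in a
  raw <- rnorm(50); clean <- rnorm(50)
  expect_equal(make_coupled_eog(raw, clean, 0.2) +
                 make_coupled_eog(raw, clean, 0.3) - raw,
               make_coupled_eog(raw, clean, 0.5), tolerance = 1e-12)
  expect_error(make_coupled_eog(1:3, 1:4, 1), "length")
})

test_that("correlation and MAE measures match their definitions", {
  x <- rnorm(100)
  expect_equal(measure_correlation(x, x), 1)
  expect_equal(measure_correlation(x, -x), -1)
  y <- c(1, -1, 1, -1); z <- c(1, 1, -1, -1)
  expect_lt(abs(measure_correlation(y, z)), 1e-12)

  expect_equal(mae(x, x), 0)
  expect_equal(mae(x, x + 3), 3)
  expect_equal(mae(c(0, 0, 0), c(1, -2, 3)), 2)
  # MAE identity: mae(raw, raw + a*clean) = |a| * mean|clean|
  a <- -0.7
  clean <- rnorm(100)
  expect_equal(mae(x, x + a * clean), abs(a) * mean(abs(clean)),
               tolerance = 1e-12)
})

test_that("the coupled set hits every target and echoes the MAE minimum", {
  set.seed(12)
  n <- 4000
  clean <- as.numeric(arima.sim(list(ar = 0.9), n))
  raw <- as.numeric(arima.sim(list(ar = 0.7), n)) + 0.35 * clean
  cs <- build_coupled_set(raw, clean)
  expect_equal(nrow(cs$entries), 5)
  expect_true(all(abs(cs$entries$achieved_rho - cs$entries$target_rho) <= 1e-6))
  expect_true(all(cs$entries$mae_vs_raw >= 0))
  expect_equal(cs$raw_clean_corr, cor(raw, clean))

  # the target closest to corr(raw, clean) needs the smallest |a| and the
  # smallest perturbation (MAE)
  closest <- which.min(abs(cs$entries$target_rho - cs$raw_clean_corr))
  expect_equal(which.min(abs(cs$entries$a)), closest)
  expect_equal(which.min(cs$entries$mae_vs_raw), closest)

  # coupled = raw + a * clean exactly
  for (i in seq_len(5))
    expect_equal(cs$signals[[i]], raw + cs$entries$a[i] * clean,
                 tolerance = 1e-12)
})
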