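# tiny config at the real epoch length so generator epochs fit
tiny_cfg_for_stage <- function()
  thnn_config(n_filters = 4, gru_hidden = 4, seq_len = 5, seed = 2)

tiny_cfg <- function(seed = 3)
  thnn_config(fs = 4, epoch_samples = 120, small_kernel = 8, small_stride = 4,
              large_kernel = 24, large_stride = 12, n_filters = 3,
              gru_hidden = 4, seq_len = 5, seed = seed)

test_that("configuration validates kernels and spans", {
  cfg <- thnn_config()
  expect_equal(cfg$small_kernel / cfg$fs, 0.5)   # 0.5 s segments
  expect_equal(cfg$large_kernel / cfg$fs, 5)     # 5 s segments
  expect_equal(cfg$epoch_samples, 3840)
  expect_error(thnn_config(small_kernel = 5000), "exceeds epoch length")
})

test_that("parameter initialization is seed-deterministic", {
  m1 <- thnn_build(thnn_config(seed = 9))
  m2 <- thnn_build(thnn_config(seed = 9))
  m3 <- thnn_build(thnn_config(seed = 10))
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  expect_gt(m1$n_parameters, 0)
  # classifier output width equals the number of stages
  expect_equal(ncol(m1$params$Wo), 5)
})

test_that("forward pass outputs probability rows for any sequence length", {
  cfg <- tiny_cfg()
  m <- thnn_build(cfg)
  x <- matrix(rnorm(5 * 120), 5, 120)
  pr <- predict(m, x)
  expect_equal(dim(pr$probabilities), c(5, 5))
  expect_equal(rowSums(pr$probabilities), rep(1, 5), tolerance = 1e-5)
  expect_true(all(pr$probabilities >= 0 & pr$probabilities <= 1))
  # predicted label is the row argmax
  expect_identical(pr$predicted,
                   STAGES5[apply(pr$probabilities, 1, which.max)])

  # degenerate single-epoch sequence
  pr1 <- predict(m, matrix(rnorm(120), 1, 120))
  expect_equal(dim(pr1$probabilities), c(1, 5))

  # batch equivariance: swapping sequences swaps outputs
  X2 <- matrix(rnorm(2 * 5 * 120), 10, 120)
  f12 <- eogcoupling:::thnn_forward_batch(m$params, cfg, X2, 2, 5)
  f21 <- eogcoupling:::thnn_forward_batch(m$params, cfg,
                                          X2[c(6:10, 1:5), ], 2, 5)
  expect_equal(unname(f12$probs), unname(f21$probs[c(6:10, 1:5), ]),
               tolerance = 1e-12)

  expect_error(predict(m, matrix(rnorm(100), 1, 100)), "epoch_samples")
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(8)
  cfg <- tiny_cfg()
  params <- eogcoupling:::thnn_init_params(cfg)
  B <- 2; L <- 5
  X <- matrix(rnorm(B * L * 120), B * L, 120)
  y <- sample(1:5, B * L, TRUE)
  lossfun <- function(p) {
    fc <- eogcoupling:::thnn_forward_batch(p, cfg, X, B, L)
    mean(-log(fc$probs[cbind(seq_along(y), y)]))
  }
  fc <- eogcoupling:::thnn_forward_batch(params, cfg, X, B, L)
  dlogits <- fc$probs
  dlogits[cbind(seq_along(y), y)] <- dlogits[cbind(seq_along(y), y)] - 1
  dlogits <- dlogits / length(y)
  g <- eogcoupling:::thnn_backward_batch(params, cfg, fc, dlogits, NULL)
  eps <- 1e-6
  for (pth in eogcoupling:::param_names(params)) {
    P0 <- eogcoupling:::get_param(params, pth)
    for (i in sample(length(P0), min(2, length(P0)))) {
      Pp <- P0; Pp[i] <- Pp[i] + eps
      Pm <- P0; Pm[i] <- Pm[i] - eps
      num <- (lossfun(eogcoupling:::set_param(params, pth, Pp)) -
                lossfun(eogcoupling:::set_param(params, pth, Pm))) / (2 * eps)
      expect_equal(eogcoupling:::get_param(g, pth)[i], num,
                   tolerance = 1e-4, label = pth)
    }
  }
})

test_that("one optimization step moves every trainable tensor", {
  set.seed(9)
  cfg <- tiny_cfg(seed = 5)
  d <- list(x = matrix(rnorm(10 * 120), 10, 120), y = sample(1:5, 10, TRUE))
  fit <- thnn(d, config = cfg, train_epochs = 1, lr = 1e-2)
  init <- thnn_build(cfg)$params
  for (pth in eogcoupling:::param_names(init)) {
    before <- eogcoupling:::get_param(init, pth)
    after <- eogcoupling:::get_param(fit$params, pth)
    expect_gt(max(abs(after - before)), 0, label = pth)
  }
})

test_that("training overfits separable synthetic stages and is deterministic", {
  d1 <- fixture_epochs(201, 40)
  d2 <- fixture_epochs(202, 40)
  fit <- thnn(list(d1, d2), config = thnn_config(seed = 1),
              train_epochs = 30)
  acc <- mean(c(predict(fit, d1, type = "class") == STAGES5[d1$y],
                predict(fit, d2, type = "class") == STAGES5[d2$y]))
  expect_gte(acc, 0.95)

  # loss decreases over training
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])

  # same seed and data: identical final loss
  fit2 <- thnn(list(d1, d2), config = thnn_config(seed = 1),
               train_epochs = 3)
  fit3 <- thnn(list(d1, d2), config = thnn_config(seed = 1),
               train_epochs = 3)
  expect_identical(fit2$history$loss, fit3$history$loss)

  # single-class data warns but proceeds
  dc <- list(x = d1$x[d1$y == d1$y[1], , drop = FALSE][1:5, ],
             y = rep(d1$y[1], 5))
  expect_warning(thnn(dc, config = tiny_cfg_for_stage(), train_epochs = 1),
                 "single class")
})

test_that("small-branch convolution is local to its kernel span", {
  cfg <- tiny_cfg()
  p <- eogcoupling:::thnn_init_params(cfg)
  idx <- eogcoupling:::conv_indices(120, cfg$small_kernel, cfg$small_stride)
  x0 <- matrix(0, 1, 120)
  x1 <- x0; x1[1, 60] <- 1      # impulse mid-epoch
  a0 <- eogcoupling:::conv_branch_forward(x0, p$W1, p$b1, idx)
  a1 <- eogcoupling:::conv_branch_forward(x1, p$W1, p$b1, idx)
  # positions whose receptive field covers sample 60
  touched <- which(apply(idx, 1, function(r) 60 %in% r))
  dA <- (a1$cache$Xc - a0$cache$Xc) %*% p$W1   # rows = conv positions (B = 1)
  changed <- which(rowSums(abs(dA)) > 0)
  expect_true(all(changed %in% touched))
  expect_lte(length(changed), ceiling(cfg$small_kernel / cfg$small_stride))
})
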