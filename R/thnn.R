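# Two-step hierarchical network for sleep staging: a two-scale 1-D CNN
# feature extractor (0.5 s and 5 s kernels at 128 Hz), feature concatenation,
# a bidirectional GRU over the epoch sequence, a residual connection from the
# CNN features, and a dense softmax over the five stages. Implemented
# directly in R: im2col convolutions through BLAS, hand-derived
# backpropagation through time for the GRU, Adam optimization.

#' Network configuration
#'
#' Defaults follow the published scale choices: a small-scale convolution
#' kernel of 64 samples (0.5 s at 128 Hz) and a large-scale kernel of 640
#' samples (5 s), over 30-s epochs of 3840 samples.
#'
#' @param fs sampling rate the network expects (Hz).
#' @param epoch_samples samples per epoch `P` (must equal 30 * fs).
#' @param n_stages number of output classes.
#' @param small_kernel,small_stride small-scale branch kernel length and
#'   stride (samples).
#' @param large_kernel,large_stride large-scale branch kernel length and
#'   stride (samples).
#' @param n_filters filters per branch.
#' @param gru_hidden GRU hidden units per direction.
#' @param seq_len epochs per training sequence `L`.
#' @param dropout dropout rate on the concatenated features during training.
#' @param seed integer seed for parameter initialization and training.
#' @return a `thnn_config` list.
#' @export
thnn_config <- function(fs = 128, epoch_samples = 30 * fs, n_stages = 5,
                        small_kernel = 64, small_stride = 8,
                        large_kernel = 640, large_stride = 64,
                        n_filters = 32, gru_hidden = 32, seq_len = 20,
                        dropout = 0, seed = 1) {
  if (max(small_kernel, large_kernel) > epoch_samples)
    stopf("kernel length (%d) exceeds epoch length (%d samples)",
          max(small_kernel, large_kernel), epoch_samples)
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  structure(list(fs = fs, epoch_samples = as.integer(epoch_samples),
                 n_stages = as.integer(n_stages),
                 small_kernel = as.integer(small_kernel),
                 small_stride = as.integer(small_stride),
                 large_kernel = as.integer(large_kernel),
                 large_stride = as.integer(large_stride),
                 n_filters = as.integer(n_filters),
                 gru_hidden = as.integer(gru_hidden),
                 seq_len = as.integer(seq_len),
                 dropout = dropout, seed = as.integer(seed)),
            class = "thnn_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))
addbias <- function(A, b) A + rep(b, each = nrow(A))

# --- convolution branch -----------------------------------------------------

conv_indices <- function(P, K, stride) {
  n_pos <- (P - K) %/% stride + 1L
  outer((seq_len(n_pos) - 1L) * stride, seq_len(K), "+")
}

# X: B_e x P batch of epochs. Returns pooled B_e x (2 nf) features
# (global average pooling || global max pooling over positions) and a cache
# for the backward pass.
conv_branch_forward <- function(X, W, b, idx) {
  B_e <- nrow(X); n_pos <- nrow(idx); K <- ncol(idx); nf <- ncol(W)
  Xc <- X[, as.vector(idx), drop = FALSE]
  dim(Xc) <- c(B_e * n_pos, K)          # rows ordered (epoch fastest, then pos)
  A <- addbias(Xc %*% W, b)
  mask <- A > 0
  H <- A * mask
  grp <- rep(seq_len(B_e), n_pos)
  avg <- rowsum(H, grp) / n_pos
  arr <- H; dim(arr) <- c(B_e, n_pos, nf)
  m2 <- aperm(arr, c(1, 3, 2)); dim(m2) <- c(B_e * nf, n_pos)
  am <- max.col(m2, ties.method = "first")
  mx <- matrix(m2[cbind(seq_along(am), am)], B_e, nf)
  list(pooled = cbind(avg, mx),
       cache = list(Xc = Xc, mask = mask, am = am, B_e = B_e,
                    n_pos = n_pos, nf = nf))
}

conv_branch_backward <- function(dpooled, cache) {
  B_e <- cache$B_e; n_pos <- cache$n_pos; nf <- cache$nf
  davg <- dpooled[, seq_len(nf), drop = FALSE]
  dmax <- dpooled[, nf + seq_len(nf), drop = FALSE]
  dH <- davg[rep(seq_len(B_e), n_pos), , drop = FALSE] / n_pos
  rows_b <- rep(seq_len(B_e), nf)
  cols_f <- rep(seq_len(nf), each = B_e)
  tgt <- cbind(rows_b + (cache$am - 1L) * B_e, cols_f)
  dH[tgt] <- dH[tgt] + as.vector(dmax)
  dA <- dH * cache$mask
  list(dW = crossprod(cache$Xc, dA), db = colSums(dA))
}

# --- GRU --------------------------------------------------------------------

# F_arr: B x L x D array of per-epoch features. One direction; `rev_time`
# runs the recurrence backwards over the epoch axis.
gru_forward <- function(F_arr, p, rev_time = FALSE) {
  B <- dim(F_arr)[1]; L <- dim(F_arr)[2]; D <- dim(F_arr)[3]
  gh <- ncol(p$Wh) / 3
  ts <- if (rev_time) L:1 else 1:L
  h <- matrix(0, B, gh)
  H <- array(0, c(B, L, gh))
  cache <- vector("list", L)
  i1 <- seq_len(gh); i2 <- gh + i1; i3 <- 2 * gh + i1
  for (t in ts) {
    x <- matrix(F_arr[, t, ], B, D)
    gx <- addbias(x %*% p$Wx, p$bx)
    gh_ <- addbias(h %*% p$Wh, p$bh)
    r <- sigmoid(gx[, i1, drop = FALSE] + gh_[, i1, drop = FALSE])
    z <- sigmoid(gx[, i2, drop = FALSE] + gh_[, i2, drop = FALSE])
    n <- tanh(gx[, i3, drop = FALSE] + r * gh_[, i3, drop = FALSE])
    h_new <- (1 - z) * n + z * h
    cache[[t]] <- list(x = x, h_prev = h, r = r, z = z, n = n,
                       ghn = gh_[, i3, drop = FALSE])
    h <- h_new
    H[, t, ] <- h
  }
  list(H = H, cache = cache, ts = ts)
}

gru_backward <- function(dH, fwd, p) {
  B <- dim(dH)[1]; L <- dim(dH)[2]; gh <- dim(dH)[3]
  D <- nrow(p$Wx)
  i1 <- seq_len(gh); i2 <- gh + i1; i3 <- 2 * gh + i1
  g <- list(Wx = p$Wx * 0, Wh = p$Wh * 0, bx = p$bx * 0, bh = p$bh * 0)
  dF <- array(0, c(B, L, D))
  dh_carry <- matrix(0, B, gh)
  for (t in rev(fwd$ts)) {
    cc <- fwd$cache[[t]]
    dh <- matrix(dH[, t, ], B, gh) + dh_carry
    dn <- dh * (1 - cc$z)
    dz <- dh * (cc$h_prev - cc$n)
    dh_prev <- dh * cc$z
    dn_pre <- dn * (1 - cc$n^2)
    dr <- dn_pre * cc$ghn
    dr_pre <- dr * cc$r * (1 - cc$r)
    dz_pre <- dz * cc$z * (1 - cc$z)
    dgx <- cbind(dr_pre, dz_pre, dn_pre)
    dgh <- cbind(dr_pre, dz_pre, dn_pre * cc$r)
    g$Wx <- g$Wx + crossprod(cc$x, dgx)
    g$Wh <- g$Wh + crossprod(cc$h_prev, dgh)
    g$bx <- g$bx + colSums(dgx)
    g$bh <- g$bh + colSums(dgh)
    dF[, t, ] <- dgx %*% t(p$Wx)
    dh_carry <- dh_prev + dgh %*% t(p$Wh)
  }
  list(grads = g, dF = dF)
}

# --- model ------------------------------------------------------------------

thnn_init_params <- function(cfg) {
  nf <- cfg$n_filters; gh <- cfg$gru_hidden
  D <- 4L * nf                      # (avg || max) x two branches
  out_dim <- 2L * gh
  gru_dir <- function() list(
    Wx = matrix(stats::rnorm(D * 3 * gh, sd = sqrt(1 / D)), D, 3 * gh),
    Wh = matrix(stats::rnorm(gh * 3 * gh, sd = sqrt(1 / gh)), gh, 3 * gh),
    bx = numeric(3 * gh), bh = numeric(3 * gh))
  with_seed(cfg$seed, list(
    W1 = matrix(stats::rnorm(cfg$small_kernel * nf,
                             sd = sqrt(2 / cfg$small_kernel)),
                cfg$small_kernel, nf),
    b1 = numeric(nf),
    W2 = matrix(stats::rnorm(cfg$large_kernel * nf,
                             sd = sqrt(2 / cfg$large_kernel)),
                cfg$large_kernel, nf),
    b2 = numeric(nf),
    gru_f = gru_dir(),
    gru_b = gru_dir(),
    Pf = matrix(stats::rnorm(D * out_dim, sd = sqrt(2 / (D + out_dim))),
                D, out_dim),
    bp = numeric(out_dim),
    Wo = matrix(stats::rnorm(out_dim * cfg$n_stages,
                             sd = sqrt(2 / (out_dim + cfg$n_stages))),
                out_dim, cfg$n_stages),
    bo = numeric(cfg$n_stages)))
}

count_params <- function(p) {
  n <- 0
  rec <- function(x) for (el in x) if (is.list(el)) rec(el) else n <<- n + length(el)
  rec(p)
  n
}

#' Build an untrained network
#'
#' Deterministically initializes all parameters from `config$seed`.
#'
#' @param config a [thnn_config].
#' @return an object of class `thnn` (untrained).
#' @export
thnn_build <- function(config = thnn_config()) {
  stopifnot(inherits(config, "thnn_config"))
  params <- thnn_init_params(config)
  structure(list(params = params, config = config,
                 n_parameters = count_params(params),
                 class_weights = rep(1, config$n_stages),
                 history = data.frame(epoch = integer(), loss = numeric()),
                 trained = FALSE),
            class = "thnn")
}

# Forward pass over a batch of sequences.
# X_batch: (B*L) x P matrix of epochs, sequence-major (epoch index varies
# fastest within a sequence). Returns probabilities and caches.
thnn_forward_batch <- function(params, cfg, X_batch, B, L,
                               dropout_mask = NULL) {
  idx1 <- conv_indices(ncol(X_batch), cfg$small_kernel, cfg$small_stride)
  idx2 <- conv_indices(ncol(X_batch), cfg$large_kernel, cfg$large_stride)
  br1 <- conv_branch_forward(X_batch, params$W1, params$b1, idx1)
  br2 <- conv_branch_forward(X_batch, params$W2, params$b2, idx2)
  F_flat <- cbind(br1$pooled, br2$pooled)        # (B*L) x 4nf
  if (!is.null(dropout_mask)) F_flat <- F_flat * dropout_mask
  D <- ncol(F_flat)
  # reshape to B x L x D: rows of F_flat are ordered epoch-within-sequence
  # fastest -> index (l, b) with l fastest; we want (b, l, d)
  F_arr <- array(0, c(B, L, D))
  F_arr[] <- aperm(array(F_flat, c(L, B, D)), c(2, 1, 3))
  fw <- gru_forward(F_arr, params$gru_f, rev_time = FALSE)
  bw <- gru_forward(F_arr, params$gru_b, rev_time = TRUE)
  gh <- cfg$gru_hidden
  H <- array(0, c(B, L, 2 * gh))
  H[, , seq_len(gh)] <- fw$H
  H[, , gh + seq_len(gh)] <- bw$H
  # flatten back to (B*L) rows in the same order as F_flat (l fastest)
  H_flat <- matrix(aperm(H, c(2, 1, 3)), B * L, 2 * gh)
  O <- H_flat + addbias(F_flat %*% params$Pf, params$bp)
  logits <- addbias(O %*% params$Wo, params$bo)
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  list(probs = probs, F_flat = F_flat, F_arr = F_arr, H_flat = H_flat, O = O,
       fw = fw, bw = bw, br1 = br1, br2 = br2, B = B, L = L)
}

thnn_backward_batch <- function(params, cfg, fwdc, dlogits, dropout_mask) {
  B <- fwdc$B; L <- fwdc$L; gh <- cfg$gru_hidden
  g <- list()
  g$Wo <- crossprod(fwdc$O, dlogits)
  g$bo <- colSums(dlogits)
  dO <- dlogits %*% t(params$Wo)
  g$Pf <- crossprod(fwdc$F_flat, dO)
  g$bp <- colSums(dO)
  dF_flat <- dO %*% t(params$Pf)
  dH_flat <- dO
  dH <- array(0, c(B, L, 2 * gh))
  dH[] <- aperm(array(dH_flat, c(L, B, 2 * gh)), c(2, 1, 3))
  bf <- gru_backward(dH[, , seq_len(gh), drop = FALSE], fwdc$fw, params$gru_f)
  bb <- gru_backward(dH[, , gh + seq_len(gh), drop = FALSE], fwdc$bw,
                     params$gru_b)
  g$gru_f <- bf$grads
  g$gru_b <- bb$grads
  dF_arr <- bf$dF + bb$dF
  dF_flat <- dF_flat + matrix(aperm(dF_arr, c(2, 1, 3)), B * L, dim(dF_arr)[3])
  if (!is.null(dropout_mask)) dF_flat <- dF_flat * dropout_mask
  nf2 <- 2L * cfg$n_filters
  c1 <- conv_branch_backward(dF_flat[, seq_len(nf2), drop = FALSE], fwdc$br1$cache)
  c2 <- conv_branch_backward(dF_flat[, nf2 + seq_len(nf2), drop = FALSE],
                             fwdc$br2$cache)
  g$W1 <- c1$dW; g$b1 <- c1$db; g$W2 <- c2$dW; g$b2 <- c2$db
  g
}

# flatten/unflatten parameter lists for the optimizer
param_names <- function(p, prefix = "") {
  out <- character(0)
  for (nm in names(p)) {
    if (is.list(p[[nm]])) out <- c(out, param_names(p[[nm]], paste0(prefix, nm, ".")))
    else out <- c(out, paste0(prefix, nm))
  }
  out
}
get_param <- function(p, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  for (s in parts) p <- p[[s]]
  p
}
set_param <- function(p, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) p[[parts]] <- value
  else p[[parts[1]]] <- set_param(p[[parts[1]]], paste(parts[-1], collapse = "."), value)
  p
}

# Normalize the many accepted input forms to list(list(x, y, id)).
as_thnn_subjects <- function(x, y = NULL, channel = NULL) {
  to_item <- function(d, nm) {
    if (inherits(d, "epoched_dataset")) {
      ch <- if (is.null(channel)) 1L else channel
      list(x = d$epochs[[ch]],
           y = match(d$labels, STAGES),
           id = if (nzchar(d$subject_id)) d$subject_id else nm)
    } else if (is.matrix(d)) {
      list(x = d, y = NULL, id = nm)
    } else if (is.list(d) && !is.null(d$x)) {
      list(x = d$x,
           y = if (is.character(d$y)) match(d$y, STAGES) else d$y,
           id = if (!is.null(d$id)) d$id else nm)
    } else stopf("cannot interpret input as epoched data")
  }
  items <- if (is.matrix(x) || inherits(x, "epoched_dataset") ||
               (is.list(x) && !is.null(x$x)))
    list(to_item(x, "subject1"))
  else lapply(seq_along(x), function(i)
    to_item(x[[i]], if (!is.null(names(x))) names(x)[i] else paste0("subject", i)))
  if (!is.null(y)) {
    if (length(items) != 1) stopf("`y` can only be given with a single input")
    items[[1]]$y <- if (is.character(y)) match(y, STAGES) else y
  }
  items
}

standardize_subject <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) s <- 1
  (x - m) / s
}

make_sequences <- function(n, seq_len) {
  if (n <= seq_len) return(list(seq_len(n)))
  starts <- seq(1L, n - seq_len + 1L, by = seq_len)
  lapply(starts, function(s) s + seq_len(seq_len) - 1L)
}

#' Fit the hierarchical staging network
#'
#' Trains the two-scale CNN + Bi-GRU classifier with class-weighted
#' cross-entropy (inverse stage frequency) and Adam. Each subject's signal is
#' standardized per recording before epoch sequences of `config$seq_len` are
#' formed. Training is fully seeded through `config$seed`.
#'
#' @param x training data: an `epoched_dataset`, a list of them, an
#'   `L x P` matrix (with `y`), or a list of `list(x =, y =)` items (one per
#'   subject).
#' @param y stage labels when `x` is a single matrix (characters in
#'   `W/N1/N2/N3/REM` or integer 1..5).
#' @param config a [thnn_config].
#' @param channel channel name/index used when `x` contains multichannel
#'   epoched datasets.
#' @param train_epochs passes over the training sequences.
#' @param batch_size sequences per optimization step.
#' @param lr Adam learning rate.
#' @param validation optional held-out data in any accepted form; when given,
#'   the parameters with the best validation loss are returned.
#' @param patience early-stopping patience (validation epochs without
#'   improvement) when `validation` is given.
#' @param verbose print per-epoch losses.
#' @return a fitted object of class `thnn` with elements `params`, `config`,
#'   `history` (per-epoch loss), `class_weights`, `n_parameters`.
#' @seealso [predict.thnn]
#' @export
thnn <- function(x, y = NULL, config = thnn_config(), channel = NULL,
                 train_epochs = 8, batch_size = 8, lr = 1e-3,
                 validation = NULL, patience = 10, verbose = FALSE) {
  subjects <- as_thnn_subjects(x, y, channel)
  if (!length(subjects)) stopf("no training subjects")
  for (s in subjects) if (is.null(s$y)) stopf("training data must be labelled")
  cfg <- config
  P <- cfg$epoch_samples
  for (s in subjects)
    if (ncol(s$x) != P)
      stopf("epoch length %d does not match config epoch_samples %d",
            ncol(s$x), P)
  # class weights from pooled training labels
  all_y <- unlist(lapply(subjects, `[[`, "y"))
  counts <- tabulate(all_y, nbins = cfg$n_stages)
  if (sum(counts > 0) < 2)
    warnf("training data contains a single class; proceeding anyway")
  w <- ifelse(counts > 0, sum(counts) / (sum(counts > 0) * pmax(counts, 1)), 0)
  # standardize per subject, build sequences
  seqs <- list()
  for (s in subjects) {
    xs <- standardize_subject(s$x)
    for (ix in make_sequences(nrow(xs), cfg$seq_len))
      seqs[[length(seqs) + 1L]] <- list(x = xs[ix, , drop = FALSE], y = s$y[ix])
  }
  lens <- vapply(seqs, function(s) nrow(s$x), integer(1))

  model <- thnn_build(cfg)
  params <- model$params
  paths <- param_names(params)
  mstate <- vstate <- lapply(paths, function(pth) get_param(params, pth) * 0)
  names(mstate) <- names(vstate) <- paths
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  val_items <- if (!is.null(validation)) as_thnn_subjects(validation, channel = channel)
  best_val <- Inf; best_params <- NULL; stale <- 0L
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_loss = numeric())

  run_epoch_loss <- function(params, items) {
    tot <- 0; n <- 0
    for (s in items) {
      xs <- standardize_subject(s$x)
      pr <- thnn_forward_epochs(params, cfg, xs)$probs
      keep <- !is.na(s$y)
      pl <- pmax(pr[cbind(seq_len(nrow(pr)), s$y)], 1e-12)
      tot <- tot + sum(-log(pl[keep])); n <- n + sum(keep)
    }
    tot / max(n, 1)
  }

  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(train_epochs)) {
      ord <- sample.int(length(seqs))
      # group shuffled sequences of equal length into batches
      ep_loss <- 0; ep_wsum <- 0
      by_len <- split(ord, lens[ord])
      batches <- list()
      for (grp in by_len) {
        ks <- split(grp, ceiling(seq_along(grp) / batch_size))
        batches <- c(batches, unname(ks))
      }
      for (bt in batches[sample.int(length(batches))]) {
        B <- length(bt); L <- nrow(seqs[[bt[1]]]$x)
        X_batch <- do.call(rbind, lapply(bt, function(k) seqs[[k]]$x))
        yv <- unlist(lapply(bt, function(k) seqs[[k]]$y))
        dmask <- if (cfg$dropout > 0)
          matrix(stats::rbinom(B * L * 4 * cfg$n_filters, 1, 1 - cfg$dropout) /
                   (1 - cfg$dropout), B * L, 4 * cfg$n_filters)
        fc <- thnn_forward_batch(params, cfg, X_batch, B, L, dmask)
        wt <- w[yv]
        pl <- pmax(fc$probs[cbind(seq_along(yv), yv)], 1e-12)
        loss <- sum(wt * -log(pl)) / sum(wt)
        ep_loss <- ep_loss + loss * sum(wt); ep_wsum <- ep_wsum + sum(wt)
        dlogits <- fc$probs
        dlogits[cbind(seq_along(yv), yv)] <-
          dlogits[cbind(seq_along(yv), yv)] - 1
        dlogits <- dlogits * (wt / sum(wt))
        g <- thnn_backward_batch(params, cfg, fc, dlogits, dmask)
        step <- step + 1L
        for (pth in paths) {
          gr <- get_param(g, pth)
          mstate[[pth]] <- beta1 * mstate[[pth]] + (1 - beta1) * gr
          vstate[[pth]] <- beta2 * vstate[[pth]] + (1 - beta2) * gr^2
          mhat <- mstate[[pth]] / (1 - beta1^step)
          vhat <- vstate[[pth]] / (1 - beta2^step)
          params <- set_param(params, pth,
                              get_param(params, pth) -
                                lr * mhat / (sqrt(vhat) + eps))
        }
      }
      mean_loss <- ep_loss / max(ep_wsum, 1e-12)
      vl <- NA_real_
      if (!is.null(val_items)) {
        vl <- run_epoch_loss(params, val_items)
        if (vl < best_val - 1e-6) {
          best_val <- vl; best_params <- params; stale <- 0L
        } else stale <- stale + 1L
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean_loss, val_loss = vl))
      if (verbose)
        cat(sprintf("epoch %d: loss %.4f%s\n", ep, mean_loss,
                    if (is.na(vl)) "" else sprintf(" val %.4f", vl)))
      if (!is.null(val_items) && stale >= patience) break
    }
  })
  if (!is.null(best_params)) params <- best_params
  model$params <- params
  model$history <- history
  model$class_weights <- w
  model$trained <- TRUE
  model
}

# Forward over a subject's full epoch matrix using prediction windows that
# cover every epoch (last window right-aligned; later windows overwrite the
# overlap). Returns probabilities and the concatenated CNN features.
thnn_forward_epochs <- function(params, cfg, x) {
  n <- nrow(x)
  Lw <- min(cfg$seq_len, n)
  starts <- unique(c(seq(1L, max(1L, n - Lw + 1L), by = Lw), n - Lw + 1L))
  probs <- matrix(NA_real_, n, cfg$n_stages)
  feats <- matrix(NA_real_, n, 4L * cfg$n_filters)
  for (s in starts) {
    ix <- s + seq_len(Lw) - 1L
    fc <- thnn_forward_batch(params, cfg, x[ix, , drop = FALSE], 1L, Lw)
    probs[ix, ] <- fc$probs
    feats[ix, ] <- fc$F_flat
  }
  list(probs = probs, features = feats)
}

#' Predict sleep stages
#'
#' @param object a fitted (or built) `thnn` model.
#' @param newdata an `epoched_dataset`, an `L x P` matrix, or a
#'   `list(x =, y =)` item.
#' @param channel channel used when `newdata` is multichannel.
#' @param type `"prob"` for the full `stage_predictions` object, `"class"`
#'   for the label vector, `"features"` for the per-epoch concatenated CNN
#'   feature matrix (the input of the sequence learner).
#' @param ... unused.
#' @return see `type`; the default is a `stage_predictions` object with
#'   `probabilities` (rows on the simplex), `predicted` (argmax labels, ties
#'   broken toward the lower stage index) and `true` when labels are
#'   available.
#' @export
predict.thnn <- function(object, newdata, channel = NULL,
                         type = c("prob", "class", "features"), ...) {
  type <- match.arg(type)
  item <- as_thnn_subjects(newdata, channel = channel)[[1]]
  if (ncol(item$x) != object$config$epoch_samples)
    stopf("epoch length %d does not match config epoch_samples %d",
          ncol(item$x), object$config$epoch_samples)
  xs <- standardize_subject(item$x)
  fe <- thnn_forward_epochs(object$params, object$config, xs)
  if (type == "features") return(fe$features)
  pred <- STAGES[apply(fe$probs, 1L, which.max)]
  if (type == "class") return(pred)
  colnames(fe$probs) <- STAGES
  structure(list(probabilities = fe$probs, predicted = pred,
                 true = if (!is.null(item$y)) STAGES[item$y]),
            class = "stage_predictions")
}

#' @export
print.stage_predictions <- function(x, ...) {
  cat(sprintf("<stage_predictions> %d epochs\n", length(x$predicted)))
  print(table(factor(x$predicted, levels = STAGES)))
  if (!is.null(x$true))
    cat(sprintf("  agreement with truth: %.3f\n",
                mean(x$predicted == x$true)))
  invisible(x)
}

#' @export
print.thnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<thnn> %s, %d parameters\n",
              if (x$trained) "trained" else "untrained", x$n_parameters))
  cat(sprintf("  branches: kernel %d (%.1f s) stride %d | kernel %d (%.1f s) stride %d, %d filters\n",
              cfg$small_kernel, cfg$small_kernel / cfg$fs, cfg$small_stride,
              cfg$large_kernel, cfg$large_kernel / cfg$fs, cfg$large_stride,
              cfg$n_filters))
  cat(sprintf("  Bi-GRU hidden %d/direction, sequence length %d epochs\n",
              cfg$gru_hidden, cfg$seq_len))
  if (nrow(x$history))
    cat(sprintf("  final training loss: %.4f (%d epochs)\n",
                x$history$loss[nrow(x$history)], nrow(x$history)))
  invisible(x)
}

#' @export
summary.thnn <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("training history:\n")
    print(object$history, row.names = FALSE)
  }
  cat("class weights:", sprintf("%.3f", object$class_weights), "\n")
  invisible(object)
}

#' @export
plot.thnn <- function(x, ...) {
  if (!nrow(x$history)) stop("no training history to plot", call. = FALSE)
  graphics::plot(x$history$epoch, x$history$loss, type = "b", pch = 19,
       xlab = "training epoch", ylab = "weighted cross-entropy loss", ...)
  if (any(!is.na(x$history$val_loss)))
    graphics::lines(x$history$epoch, x$history$val_loss, type = "b", pch = 1, lty = 2)
  invisible(x)
}
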