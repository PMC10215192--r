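# Orchestration of the full study on a synthetic cohort: simulate ->
# preprocess -> separate -> couple -> (per signal condition) LOSO train /
# evaluate -> metric and significance tables.

#' Experiment configuration
#'
#' One object drives the whole pipeline; it is plain-list serializable (see
#' [save_experiment_config]).
#'
#' @param n_subjects cohort size (>= 2 for LOSO).
#' @param n_epochs 30-s epochs per subject (default 240, i.e. 2 h).
#' @param gen_fs generation sampling rate (Hz).
#' @param line_freq notch frequency (50 or 60 Hz).
#' @param target_fs staging sampling rate after resampling (Hz).
#' @param targets coupled-EOG target correlation levels.
#' @param side which EOG side to analyse: "left" (E1 vs Fp1) or "right"
#'   (E2 vs Fp2).
#' @param conditions signal conditions to stage: the coupled targets plus
#'   `rawEOG` and `EEG`.
#' @param sobi_lags lag set for [sobi].
#' @param eog_threshold component-removal correlation threshold.
#' @param thnn a [thnn_config] (its seed is re-derived per fold).
#' @param train_epochs,batch_size,lr training hyperparameters per fold.
#' @param seed master seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(n_subjects = 6, n_epochs = 240, gen_fs = 256,
                              line_freq = 50, target_fs = 128,
                              targets = c(0.0, 0.1, 0.2, 0.3, 0.5),
                              side = c("left", "right"),
                              conditions = NULL,
                              sobi_lags = 1:100, eog_threshold = 0.7,
                              thnn = thnn_config(), train_epochs = 5,
                              batch_size = 8, lr = 1e-3, seed = 1) {
  side <- match.arg(side)
  if (is.null(conditions))
    conditions <- c(sprintf("rho_%.1f", targets), "rawEOG", "EEG")
  structure(list(n_subjects = n_subjects, n_epochs = n_epochs,
                 gen_fs = gen_fs, line_freq = line_freq,
                 target_fs = target_fs, targets = targets, side = side,
                 conditions = conditions, sobi_lags = sobi_lags,
                 eog_threshold = eog_threshold, thnn = thnn,
                 train_epochs = train_epochs, batch_size = batch_size,
                 lr = lr, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Write/read an experiment configuration as YAML
#'
#' @param config an [experiment_config].
#' @param path YAML file path.
#' @return `path` (write) or the restored `experiment_config` (read).
#' @export
save_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  plain <- unclass(config)
  plain$thnn <- unclass(plain$thnn)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname save_experiment_config
#' @export
load_experiment_config <- function(path) {
  plain <- yaml::read_yaml(path)
  plain$thnn <- do.call(thnn_config, plain$thnn)
  do.call(experiment_config, plain)
}

# Simulate, preprocess, separate and couple one subject. Returns the
# per-condition single-channel signals at target_fs plus the epoch labels
# and the coupling summary.
prepare_subject <- function(id, cfg) {
  subj <- make_synthetic_subject(id, n_epochs = cfg$n_epochs, fs = cfg$gen_fs,
                                 seed = cfg$seed + 17L * match(id, paste0("S", seq_len(cfg$n_subjects))))
  rec <- preprocess_recording(subj$recording, line_freq = cfg$line_freq,
                              target_fs = cfg$target_fs)
  sep <- sobi(rec, lags = cfg$sobi_lags)
  clean <- remove_eog_components(sep, rec$samples[c("E1", "E2"), ,
                                                  drop = FALSE],
                                 threshold = cfg$eog_threshold,
                                 fs = cfg$target_fs)
  eog_ch <- if (cfg$side == "left") "E1" else "E2"
  eeg_ch <- if (cfg$side == "left") "Fp1" else "Fp2"
  raw_eog <- channel(rec, eog_ch)
  clean_eeg <- channel(clean, eeg_ch)
  cset <- build_coupled_set(raw_eog, clean_eeg, targets = cfg$targets)
  signals <- c(cset$signals, list(rawEOG = raw_eog, EEG = clean_eeg))
  list(id = id, signals = signals, labels = subj$hypnogram$labels,
       coupling = cbind(subject = id, side = cfg$side, cset$entries,
                        raw_clean_corr = cset$raw_clean_corr))
}

signal_to_epochs <- function(sig, labels, fs, epoch_seconds = 30) {
  P <- as.integer(epoch_seconds * fs)
  L <- min(length(sig) %/% P, length(labels))
  list(x = matrix(sig[seq_len(L * P)], L, P, byrow = TRUE),
       y = match(labels[seq_len(L)], STAGES))
}

#' Run the full coupled-EOG staging experiment
#'
#' Simulates a synthetic cohort, conditions and separates each recording,
#' builds the coupled-EOG set per subject, and for every signal condition
#' (each coupled target, the raw EOG, the clean EEG) runs leave-one-subject-
#' out training and evaluation of the staging network, aggregating the
#' metric suite and the chi-square feature significance analysis.
#'
#' @param config an [experiment_config].
#' @param verbose print progress.
#' @return a `psg_experiment` object with elements `coupling` (per-subject
#'   calibration table: a, achieved rho, MAE), `metrics` (per-condition
#'   pooled metric suite plus mean per-subject accuracy), `significance`
#'   (per-condition chi-square summary), `confusions` (pooled confusion
#'   matrix per condition), `folds` (train/test ids per fold) and `config`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  ids <- paste0("S", seq_len(config$n_subjects))
  say <- function(...) if (verbose) cat(sprintf(...))
  say("preparing %d subjects...\n", length(ids))
  cohort <- lapply(ids, function(id) {
    say("  subject %s\n", id)
    prepare_subject(id, config)
  })
  names(cohort) <- ids
  coupling <- do.call(rbind, lapply(cohort, `[[`, "coupling"))
  rownames(coupling) <- NULL
  folds <- loso_folds(ids)

  metrics_rows <- list(); sig_rows <- list(); confusions <- list()
  per_subject_acc <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    say("condition %s\n", cond)
    epoched <- lapply(cohort, function(s) {
      if (!cond %in% names(s$signals))
        stopf("condition '%s' not among prepared signals (%s)",
              cond, paste(names(s$signals), collapse = ", "))
      signal_to_epochs(s$signals[[cond]], s$labels, config$target_fs)
    })
    # every stage must occur somewhere in every training split
    pooled_y <- unlist(lapply(epoched, `[[`, "y"))
    if (length(unique(pooled_y)) < length(STAGES))
      stopf("stage(s) %s absent from the whole cohort; enlarge n_epochs",
            paste(STAGES[setdiff(1:5, unique(pooled_y))], collapse = ", "))
    true_all <- character(0); pred_all <- character(0)
    feats_all <- NULL; acc_subj <- numeric(0)
    for (fi in seq_along(folds)) {
      fold <- folds[[fi]]
      cfg_t <- config$thnn
      cfg_t$seed <- config$seed + 1000L * ci + fi
      fit <- thnn(epoched[fold$train], config = cfg_t,
                  train_epochs = config$train_epochs,
                  batch_size = config$batch_size, lr = config$lr)
      test <- epoched[[fold$test]]
      pr <- predict(fit, test)
      fe <- predict(fit, test, type = "features")
      true_all <- c(true_all, STAGES[test$y])
      pred_all <- c(pred_all, pr$predicted)
      feats_all <- rbind(feats_all, fe)
      acc_subj <- c(acc_subj, mean(pr$predicted == STAGES[test$y]))
      say("  fold %d (%s): accuracy %.3f\n", fi, fold$test,
          acc_subj[length(acc_subj)])
    }
    mr <- suppressMessages(compute_metrics(true_all, pred_all))
    sig <- suppressMessages(suppressWarnings(
      chi_square_features(feats_all, true_all)))
    metrics_rows[[cond]] <- data.frame(
      condition = cond, accuracy = mr$accuracy, kappa = mr$kappa,
      f1_macro = mr$f1_macro, specificity_macro = mr$specificity_macro,
      mean_subject_accuracy = mean(acc_subj),
      t(as.matrix(mr$per_stage_precision)), check.names = FALSE)
    sig_rows[[cond]] <- data.frame(condition = cond,
                                   mean_chi2 = sig$mean_chi2,
                                   p_bonferroni = sig$p_bonferroni)
    confusions[[cond]] <- mr$confusion
    per_subject_acc[[cond]] <- acc_subj
  }
  metrics <- do.call(rbind, metrics_rows); rownames(metrics) <- NULL
  significance <- do.call(rbind, sig_rows); rownames(significance) <- NULL
  structure(list(coupling = coupling, metrics = metrics,
                 significance = significance, confusions = confusions,
                 per_subject_accuracy = per_subject_acc,
                 folds = folds, config = config),
            class = "psg_experiment")
}

#' @export
print.psg_experiment <- function(x, digits = 3, ...) {
  cat(sprintf("<psg_experiment> %d subjects x %d epochs, side: %s\n",
              x$config$n_subjects, x$config$n_epochs, x$config$side))
  cat("\ncoupling calibration (per subject):\n")
  print(format(x$coupling, digits = digits), row.names = FALSE)
  cat("\nstaging metrics (pooled over LOSO test sets):\n")
  print(format(x$metrics, digits = digits), row.names = FALSE)
  cat("\nfeature-stage association:\n")
  print(format(x$significance, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
plot.psg_experiment <- function(x, ...) {
  m <- x$metrics
  is_rho <- grepl("^rho_", m$condition)
  rho <- as.numeric(sub("rho_", "", m$condition[is_rho]))
  ord <- order(rho)
  graphics::plot(rho[ord], m$accuracy[is_rho][ord], type = "b", pch = 19,
       xlab = "target correlation with clean EEG",
       ylab = "LOSO staging accuracy",
       ylim = range(m$accuracy), ...)
  graphics::abline(h = m$accuracy[m$condition == "rawEOG"], lty = 2, col = "grey40")
  graphics::abline(h = m$accuracy[m$condition == "EEG"], lty = 3, col = "grey40")
  graphics::legend("bottomright", lty = c(1, 2, 3), pch = c(19, NA, NA),
         col = c("black", "grey40", "grey40"),
         legend = c("coupled EOG", "raw EOG", "clean EEG"), bty = "n")
  invisible(x)
}
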