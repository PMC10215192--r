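# Leave-one-subject-out protocol, the staging metric suite (accuracy, Cohen's
# kappa, macro F1, macro specificity, per-stage precision), and the
# chi-square significance analysis of network features versus stage labels.

#' Leave-one-subject-out folds
#'
#' @param subjects vector of subject identifiers (>= 2, unique).
#' @return list of folds, each `list(train =, test =)`; every subject is the
#'   test set exactly once and train/test are subject-disjoint.
#' @export
loso_folds <- function(subjects) {
  subjects <- as.character(subjects)
  if (length(subjects) < 2) stopf("LOSO needs at least 2 subjects")
  if (anyDuplicated(subjects)) stopf("subject ids must be unique")
  lapply(seq_along(subjects), function(i)
    list(train = subjects[-i], test = subjects[i]))
}

#' Staging metric suite
#'
#' Computes the full agreement report between true and predicted stage
#' labels: overall accuracy, Cohen's kappa (chance agreement from the
#' marginals), macro F1 over the stages present in the truth, macro
#' specificity (mean over stages of TN / (TN + FP)), per-stage precision
#' (0 when a stage is never predicted, noted via a message), and the 5x5
#' confusion matrix.
#'
#' @param true,predicted equal-length stage label vectors.
#' @param stages stage vocabulary (fixes the confusion-matrix order).
#' @return a `metrics_report` list.
#' @export
compute_metrics <- function(true, predicted, stages = STAGES) {
  if (length(true) != length(predicted))
    stopf("label vectors differ in length (%d vs %d)",
          length(true), length(predicted))
  if (!length(true)) stopf("need at least one epoch")
  conf <- table(true = factor(true, levels = stages),
                predicted = factor(predicted, levels = stages))
  n <- sum(conf)
  acc <- sum(diag(conf)) / n
  po <- acc
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) 1 else (po - pe) / (1 - pe)
  colsum <- colSums(conf); rowsum <- rowSums(conf)
  never <- stages[colsum == 0 & rowsum > 0]
  if (length(never))
    message("stage(s) never predicted (precision set to 0): ",
            paste(never, collapse = ", "))
  precision <- ifelse(colsum > 0, diag(conf) / colsum, 0)
  recall <- ifelse(rowsum > 0, diag(conf) / rowsum, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  present <- rowsum > 0
  f1_macro <- mean(f1[present])
  tn <- vapply(seq_along(stages), function(k)
    n - rowsum[k] - colsum[k] + conf[k, k], numeric(1))
  fp <- colsum - diag(conf)
  spec_ok <- (tn + fp) > 0
  specificity_macro <- mean((tn / (tn + fp))[spec_ok])
  structure(list(accuracy = acc, kappa = kappa, f1_macro = f1_macro,
                 specificity_macro = specificity_macro,
                 per_stage_precision = stats::setNames(as.numeric(precision),
                                                       stages),
                 confusion = conf),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metrics_report> accuracy %.3f | kappa %.3f | macro F1 %.3f | macro specificity %.3f\n",
              x$accuracy, x$kappa, x$f1_macro, x$specificity_macro))
  cat("per-stage precision:\n")
  print(round(x$per_stage_precision, digits))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

# Quantile-bin one feature into at most n_bins bins, then merge adjacent
# bins until every expected count (under independence with `labels`) is at
# least `min_expected`. Returns the bin assignment factor or NULL when the
# feature is degenerate (constant).
quantile_bins <- function(feature, labels, n_bins, min_expected = 5) {
  qs <- stats::quantile(feature, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  brk <- unique(qs)
  if (length(brk) < 2) return(NULL)
  bins <- cut(feature, breaks = brk, include.lowest = TRUE, labels = FALSE)
  lab_f <- factor(labels)
  repeat {
    tab <- table(bins, lab_f)
    if (nrow(tab) <= 2) break
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (min(expected) >= min_expected) break
    # merge the smallest bin into its smaller neighbour
    k <- which.min(rowSums(tab))
    into <- if (k == 1) 2 else if (k == nrow(tab)) k - 1 else
      if (rowSums(tab)[k - 1] <= rowSums(tab)[k + 1]) k - 1 else k + 1
    old <- sort(unique(bins))
    bins[bins == old[k]] <- old[into]
    bins <- match(bins, sort(unique(bins)))
  }
  if (length(unique(bins)) < 2) return(NULL)
  tab <- table(bins, lab_f)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (min(expected) < min_expected)
    message(sprintf(paste("expected counts below %g remain after merging",
                          "(rare stage); chi-square is approximate"),
                    min_expected))
  bins
}

#' Chi-square association between network features and stage labels
#'
#' Each feature is discretized into quantile bins (adjacent bins merged until
#' all expected counts reach 5, stopping at two bins; if a rare stage still
#' leaves small expected counts the statistic is computed anyway with a
#' note), a feature-bin x stage contingency table is formed, and the Pearson chi-square statistic with its p-value is computed
#' per feature. A combined summary reports the mean statistic and the
#' Bonferroni-adjusted minimum p-value. A constant feature yields a
#' degenerate table and is reported as p = 1 with a warning.
#'
#' @param features epoch x feature numeric matrix (or vector).
#' @param labels per-epoch stage labels.
#' @param n_bins number of quantile bins per feature (default 10).
#' @return a `chisq_features` object: `per_feature` data frame
#'   (feature, chi2, dof, p_value), `mean_chi2`, `p_bonferroni`, `binning`.
#' @export
chi_square_features <- function(features, labels, n_bins = 10) {
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  if (nrow(features) != length(labels))
    stopf("features have %d rows but there are %d labels",
          nrow(features), length(labels))
  nm <- colnames(features)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(features)))
  res <- lapply(seq_len(ncol(features)), function(j) {
    bins <- quantile_bins(features[, j], labels, n_bins)
    if (is.null(bins)) {
      warnf("feature '%s' is (near-)constant; no association measurable", nm[j])
      return(data.frame(feature = nm[j], chi2 = 0, dof = 1, p_value = 1))
    }
    tab <- table(bins, factor(labels))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi2 <- sum((tab - expected)^2 / expected)
    dof <- (nrow(tab) - 1) * (ncol(tab) - 1)
    if (dof < 1) {
      warnf("feature '%s': degenerate contingency table", nm[j])
      return(data.frame(feature = nm[j], chi2 = 0, dof = 1, p_value = 1))
    }
    data.frame(feature = nm[j], chi2 = chi2, dof = dof,
               p_value = stats::pchisq(chi2, dof, lower.tail = FALSE))
  })
  per_feature <- do.call(rbind, res)
  structure(list(per_feature = per_feature,
                 mean_chi2 = mean(per_feature$chi2),
                 p_bonferroni = min(1, min(per_feature$p_value) *
                                      nrow(per_feature)),
                 binning = sprintf("%d quantile bins, adjacent bins merged to expected >= 5",
                                   n_bins)),
            class = "chisq_features")
}

#' @export
print.chisq_features <- function(x, ...) {
  cat(sprintf("<chisq_features> %d feature(s); mean chi2 = %.2f; Bonferroni min p = %.3g\n",
              nrow(x$per_feature), x$mean_chi2, x$p_bonferroni))
  cat("  binning:", x$binning, "\n")
  invisible(x)
}
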