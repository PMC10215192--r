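# Brute-force metric oracle: everything computed by explicit counting loops,
# independent of the package implementation.
brute_metrics <- function(true, pred, stages = STAGES5) {
  n <- length(true)
  acc <- sum(true == pred) / n
  po <- acc
  pe <- 0
  for (s in stages) pe <- pe + (sum(true == s) / n) * (sum(pred == s) / n)
  kappa <- (po - pe) / (1 - pe)
  prec <- rec <- f1 <- spec <- numeric(0)
  for (s in stages) {
    tp <- sum(true == s & pred == s)
    fp <- sum(true != s & pred == s)
    fn <- sum(true == s & pred != s)
    tn <- n - tp - fp - fn
    p_s <- if (tp + fp > 0) tp / (tp + fp) else 0
    r_s <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec[s] <- p_s; rec[s] <- r_s
    f1[s] <- if (p_s + r_s > 0) 2 * p_s * r_s / (p_s + r_s) else 0
    spec[s] <- if (tn + fp > 0) tn / (tn + fp) else NA
  }
  present <- stages[vapply(stages, function(s) any(true == s), logical(1))]
  list(accuracy = acc, kappa = kappa, f1_macro = mean(f1[present]),
       specificity_macro = mean(spec, na.rm = TRUE), precision = prec)
}

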