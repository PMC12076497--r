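# Independent brute-force oracles used to validate the metric
# implementations. Each oracle takes a deliberately different computational
# route from the package code (explicit pairwise loops, threshold sweeps,
# term-by-term sums, full sign-pattern enumeration).

# AUC by explicit pairwise concordance counting, ties counted one half.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Area under the PR curve by an explicit sweep over distinct thresholds
# (step integration), minus the positive base rate.
oracle_delta_auc_pr <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / sum(labels)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap - sum(labels) / length(labels)
}

# BEDROC by term-by-term exponential rank sums, normalized by the sums for
# the best and worst possible orderings computed the same explicit way.
oracle_bedroc <- function(scores, labels, alpha = 20) {
  n <- length(scores)
  npos <- sum(labels)
  r <- n + 1 - rank(scores, ties.method = "average")
  w <- 0
  for (ri in r[labels == 1]) w <- w + exp(-alpha * ri / n)
  wmax <- 0
  for (i in seq_len(npos)) wmax <- wmax + exp(-alpha * i / n)
  wmin <- 0
  for (i in (n - npos + 1):n) wmin <- wmin + exp(-alpha * i / n)
  (w - wmin) / (wmax - wmin)
}

# Balanced accuracy and MCC from an explicitly tabulated confusion matrix.
oracle_bacc_mcc <- function(scores, labels, threshold = 0.5) {
  pred <- factor(as.integer(scores >= threshold), levels = c(0, 1))
  truth <- factor(labels, levels = c(0, 1))
  tab <- table(pred, truth)
  tn <- tab["0", "0"]; fp <- tab["1", "0"]
  fn <- tab["0", "1"]; tp <- tab["1", "1"]
  bacc <- (tp / (tp + fn) + tn / (tn + fp)) / 2
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(bacc = bacc, mcc = mcc)
}

# Two-sided paired Wilcoxon p by full enumeration of all 2^n sign patterns
# of the nonzero differences (average ranks for ties), using the same
# doubled-rank integer statistic as the package so comparisons are exact.
oracle_wilcoxon_enum <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d))))
  total <- sum(r2)
  obs <- abs(2L * sum(r2[d > 0]) - total)
  pats <- expand.grid(rep(list(c(0L, 1L)), n))
  w2 <- as.matrix(pats) %*% r2
  mean(abs(2L * w2 - total) >= obs)
}
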