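# Virtual-screening evaluation metrics and the paired significance test
# used for model comparison: ROC-AUC, delta AUC-PR, BEDROC, balanced
# accuracy, MCC, and an exact paired Wilcoxon signed-rank test.

check_binary_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    fsm_stop("dimension_mismatch", "scores and labels differ in length")
  }
  if (!all(labels %in% c(0, 1))) {
    fsm_stop("invalid_input", "labels must be 0/1")
  }
  if (all(labels == 1) || all(labels == 0)) {
    fsm_stop("one_class_only", "metric undefined: only one class present")
  }
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability via average ranks,
#' so tied scores count one half.
#'
#' @param scores numeric prediction scores (higher = more active).
#' @param labels binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
metric_auc <- function(scores, labels) {
  check_binary_labels(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve minus the random baseline
#'
#' The PR curve is integrated by the step rule (average-precision
#' convention): thresholds sweep the distinct score values in descending
#' order and each recall increment is weighted by the precision at that
#' threshold. The random-classifier baseline, the positive fraction
#' `n_pos / n`, is subtracted; constant scores therefore give exactly 0.
#'
#' @inheritParams metric_auc
#' @return delta AUC-PR in `[-1, 1]`.
#' @export
metric_delta_auc_pr <- function(scores, labels) {
  check_binary_labels(scores, labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  n <- length(y)
  npos <- sum(y)
  # indices where a distinct-score block ends
  ends <- which(c(s[-n] != s[-1], TRUE))
  tp <- cumsum(y)[ends]
  prec <- tp / ends
  rec <- tp / npos
  ap <- sum(diff(c(0, rec)) * prec)
  ap - npos / n
}

#' Boltzmann-enhanced discrimination of the ROC curve (BEDROC)
#'
#' Early-recognition metric: actives near the top of the ranked list are
#' weighted exponentially (decay parameter `alpha`). Implemented as the
#' robust initial enhancement (the exponentially weighted rank sum of the
#' actives) normalized to `[0, 1]` by its exact discrete minimum and maximum
#' (the sums obtained when all actives are ranked last or first), so a
#' perfect ranking gives exactly 1 and the worst exactly 0. Tied scores get
#' average ranks.
#'
#' @inheritParams metric_auc
#' @param alpha positive early-recognition weight (default 20).
#' @return BEDROC in `[0, 1]`.
#' @export
metric_bedroc <- function(scores, labels, alpha = 20) {
  check_binary_labels(scores, labels)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    fsm_stop("invalid_input", "alpha must be a positive scalar")
  }
  n <- length(scores)
  npos <- sum(labels == 1)
  # rank 1 = highest score; ties -> average ranks
  r <- n + 1 - rank(scores, ties.method = "average")
  w <- sum(exp(-alpha * r[labels == 1] / n))
  q <- exp(-alpha / n)
  # geometric sums for the best (ranks 1..npos) and worst (ranks n-npos+1..n)
  wmax <- q * (1 - q^npos) / (1 - q)
  wmin <- q^(n - npos + 1) * (1 - q^npos) / (1 - q)
  (w - wmin) / (wmax - wmin)
}

#' Balanced accuracy and Matthews correlation coefficient at a threshold
#'
#' Scores at or above `threshold` are predicted active. MCC is defined as 0
#' when any confusion-matrix margin is empty.
#'
#' @inheritParams metric_auc
#' @param threshold score cutoff (default 0.5).
#' @return list with elements `bacc` and `mcc`.
#' @export
metric_bacc_mcc <- function(scores, labels, threshold = 0.5) {
  check_binary_labels(scores, labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  bacc <- (tp / (tp + fn) + tn / (tn + fp)) / 2
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(bacc = bacc, mcc = mcc)
}

#' All five evaluation metrics for one scored task
#'
#' @inheritParams metric_auc
#' @param alpha BEDROC early-recognition parameter.
#' @param threshold classification threshold for balanced accuracy and MCC.
#' @return one-row data.frame: `auc`, `delta_auc_pr`, `bedroc`, `bacc`,
#'   `mcc`, `n_pos`, `n_neg`.
#' @export
metric_vector <- function(scores, labels, alpha = 20, threshold = 0.5) {
  bm <- metric_bacc_mcc(scores, labels, threshold)
  data.frame(
    auc = metric_auc(scores, labels),
    delta_auc_pr = metric_delta_auc_pr(scores, labels),
    bedroc = metric_bedroc(scores, labels, alpha),
    bacc = bm$bacc,
    mcc = bm$mcc,
    n_pos = sum(labels == 1),
    n_neg = sum(labels == 0)
  )
}

# Paired Wilcoxon signed-rank test ---------------------------------------

#' Exact distribution of the signed-rank statistic for given rank weights
#'
#' Dynamic-programming convolution over doubled (hence integer) average
#' ranks; returns the probability vector over `2*W = 0 .. sum(2r)`.
#' @keywords internal
signrank_dist <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (w in r2) {
    g <- f / 2
    g[(w + 1L):(total + 1L)] <- g[(w + 1L):(total + 1L)] + f[1L:(total + 1L - w)] / 2
    f <- g
  }
  f
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped. For `n <= exact_limit` remaining pairs the
#' two-sided p-value is exact — computed from the full distribution of the
#' signed-rank statistic under random signs, with tied absolute differences
#' handled by average ranks, as `P(|W - mu| >= |w_obs - mu|)`. For larger
#' `n` a normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_limit maximum `n` for the exact distribution (default 25).
#' @return list with `p_value`, `statistic` (signed-rank sum of positive
#'   differences), `n_effective`, `method`.
#' @section Errors: `fewshotmol_too_few_pairs` if fewer than 5 nonzero
#'   differences remain; `fewshotmol_all_zero_differences` if `a == b`
#'   everywhere.
#' @export
paired_wilcoxon <- function(a, b, exact_limit = 25L) {
  if (length(a) != length(b)) {
    fsm_stop("dimension_mismatch", "paired vectors differ in length")
  }
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) {
    fsm_stop("all_zero_differences", "all paired differences are zero")
  }
  n <- length(d)
  if (n < 5L) {
    fsm_stop("too_few_pairs",
             sprintf("only %d nonzero pairs; need at least 5", n))
  }
  r <- rank(abs(d), ties.method = "average")
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    f <- signrank_dist(r2)
    total <- sum(r2)
    # statistic support is k/2 for k = 0..total; mean is total/4 (x2 = total/2)
    dev <- abs(4L * (0:total) - 2L * total)   # 4*|k/2 - total/4|
    obs <- abs(as.integer(round(8 * w)) - 2L * total)
    p <- sum(f[dev >= obs])
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sg2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(w - mu) - 0.5) / sqrt(sg2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal_approx"
  }
  list(p_value = min(1, p), statistic = w, n_effective = n, method = method)
}
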