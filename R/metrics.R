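# Threshold metrics, rank-based AUC with bootstrap CI, and the Mann-Whitney
# U test used to compare per-bag score distributions between models.

#' Confusion counts at a probability threshold
#'
#' A bag is called positive when its probability is greater than or equal to
#' the threshold (0.5 by default; exactly 0.5 counts as positive).
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary labels.
#' @param threshold Decision threshold.
#' @return A `ramil_confusion` list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) == 0) abort_ramil("empty input.")
  stopifnot(length(probabilities) == length(labels))
  if (!is_binary(labels)) abort_ramil("labels must be 0/1.")
  pred <- probabilities >= threshold
  pos <- labels == 1
  structure(list(TP = sum(pred & pos), FP = sum(pred & !pos),
                 FN = sum(!pred & pos), TN = sum(!pred & !pos)),
            class = "ramil_confusion")
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s is 0/0; reporting 0.", what), call. = FALSE)
    return(0)
  }
  num / den
}

#' Threshold classification metrics from confusion counts
#'
#' Standard definitions: accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' `F1 = 2*pre*rec/(pre+rec)`. Any `0/0` is reported as 0 with a warning.
#'
#' @param cc A [confusion_counts()] result (or a list with TP/FP/FN/TN).
#' @return One-row tibble with `acc`, `pre`, `rec`, `spe`, `f1` in `[0, 1]`.
#' @export
classification_metrics <- function(cc) {
  n <- cc$TP + cc$FP + cc$FN + cc$TN
  if (n == 0) abort_ramil("empty confusion counts.")
  pre <- safe_ratio(cc$TP, cc$TP + cc$FP, "precision")
  rec <- safe_ratio(cc$TP, cc$TP + cc$FN, "recall")
  spe <- safe_ratio(cc$TN, cc$TN + cc$FP, "specificity")
  f1 <- if (pre + rec == 0) {
    warning("F1 is 0/0; reporting 0.", call. = FALSE)
    0
  } else 2 * pre * rec / (pre + rec)
  tibble::tibble(acc = (cc$TP + cc$TN) / n, pre = pre, rec = rec,
                 spe = spe, f1 = f1)
}

#' Rank-based AUC (Mann-Whitney formulation)
#'
#' `AUC = (R_pos - n_pos (n_pos + 1) / 2) / (n_pos * n_neg)` with midranks,
#' i.e. the probability a random positive outscores a random negative, ties
#' counting one half.
#'
#' @param probabilities Scores.
#' @param labels Binary labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  pos <- labels == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) abort_ramil("AUC needs both classes.")
  r <- rank(probabilities)           # midranks handle ties
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile interval from a stratified bootstrap: positives and negatives
#' are resampled within class, preserving prevalence.
#'
#' @param probabilities Scores.
#' @param labels Binary labels.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed.
#' @param level Confidence level.
#' @return Named numeric `c(lower, upper)`.
#' @export
auc_ci <- function(probabilities, labels, n_boot = 2000L, seed = 1L,
                   level = 0.95) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  stats_b <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      auc_rank(probabilities[idx], labels[idx])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(stats_b, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Mann-Whitney U test
#'
#' Two-sided test that two samples come from the same distribution, via the
#' rank-sum U statistic. Uses exact enumeration over group assignments when
#' `min(n_a, n_b) <= exact_max` (valid under ties), otherwise the normal
#' approximation with the tie-corrected variance.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest smaller-group size for which the exact
#'   permutation distribution is enumerated.
#' @return List with `U` (wins of `a` over `b`, ties counting one half),
#'   `p_value` and `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8L) {
  n_a <- length(a)
  n_b <- length(b)
  if (n_a == 0 || n_b == 0) abort_ramil("both samples must be non-empty.")
  comb <- c(a, b)
  r <- rank(comb)
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (min(n_a, n_b) <= exact_max && choose(n_a + n_b, n_a) <= 5e5) {
    sets <- utils::combn(n_a + n_b, n_a)
    u_all <- apply(sets, 2, function(ix) sum(r[ix])) - n_a * (n_a + 1) / 2
    mirror <- n_a * n_b - U
    lo <- min(U, mirror)
    hi <- max(U, mirror)
    p <- mean(u_all <= lo + 1e-9) + mean(u_all >= hi - 1e-9)
    p <- min(1, p)
    method <- "exact enumeration"
  } else {
    n <- n_a + n_b
    ties <- table(comb)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    z <- (U - n_a * n_b / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(U = U, p_value = p, method = method)
}

#' ROC curve points
#'
#' @param probabilities Scores.
#' @param labels Binary labels.
#' @return Tibble with `threshold`, `fpr`, `tpr`, one row per distinct
#'   threshold (plus the extremes).
#' @export
roc_points <- function(probabilities, labels) {
  th <- c(Inf, sort(unique(probabilities), decreasing = TRUE), -Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  purrr::map_dfr(th, function(t) {
    pred <- probabilities >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred & labels == 0) / n_neg,
                   tpr = sum(pred & labels == 1) / n_pos)
  })
}
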