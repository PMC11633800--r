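#' Evaluate a fitted model on a set of bags
#'
#' Computes threshold metrics at 0.5, rank-based AUC with a stratified
#' bootstrap confidence interval, and retains the per-bag probabilities.
#'
#' @param model A `ramil_model`.
#' @param bags Bag tibble with labels.
#' @param threshold Decision threshold.
#' @param n_boot Bootstrap resamples for the AUC interval.
#' @param seed Seed for the bootstrap.
#' @return A `ramil_eval` list: `metrics` (one-row tibble), `auc`, `auc_ci`,
#'   `n_pos`, `n_neg`, `probs` (per-bag tibble).
#' @export
evaluate_model <- function(model, bags, threshold = 0.5, n_boot = 2000L,
                           seed = 1L) {
  pr <- predict(model, bags)
  cc <- confusion_counts(pr$prob, pr$label, threshold)
  structure(
    list(
      metrics = classification_metrics(cc),
      confusion = cc,
      auc = auc_rank(pr$prob, pr$label),
      auc_ci = auc_ci(pr$prob, pr$label, n_boot, seed),
      n_pos = sum(pr$label == 1), n_neg = sum(pr$label == 0),
      threshold = threshold,
      probs = pr
    ),
    class = "ramil_eval"
  )
}

#' @export
print.ramil_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<ramil_eval> %d bags (%d pos / %d neg)\n  acc %.3f | auc %.3f (%.3f, %.3f) | pre %.3f | rec %.3f | spe %.3f | f1 %.3f\n",
    x$n_pos + x$n_neg, x$n_pos, x$n_neg, m$acc, x$auc,
    x$auc_ci["lower"], x$auc_ci["upper"], m$pre, m$rec, m$spe, m$f1))
  invisible(x)
}

#' Long-format metrics of an evaluation
#' @param x A `ramil_eval`.
#' @param ... Unused.
#' @return Tibble with `metric`, `value`.
#' @method tidy ramil_eval
#' @export
tidy.ramil_eval <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::mutate(x$metrics, auc = x$auc),
    dplyr::everything(), names_to = "metric", values_to = "value")
}

#' One-row evaluation summary
#' @param x A `ramil_eval`.
#' @param ... Unused.
#' @return One-row tibble of all metrics plus the AUC interval and sizes.
#' @method glance ramil_eval
#' @export
glance.ramil_eval <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(auc = x$auc, auc_lower = x$auc_ci[["lower"]],
                   auc_upper = x$auc_ci[["upper"]],
                   n_pos = x$n_pos, n_neg = x$n_neg)
  )
}

eval_row <- function(ev) {
  dplyr::bind_cols(ev$metrics,
                   tibble::tibble(auc = ev$auc,
                                  auc_lower = ev$auc_ci[["lower"]],
                                  auc_upper = ev$auc_ci[["upper"]]))
}

#' Sweep the ranking cutoff C
#'
#' Retrains the model once per candidate `C` under a shared seed (identical
#' splits and initialization) and evaluates each on the same test bags.
#'
#' @param train_bags,test_bags Bag tibbles.
#' @param c_values Candidate cutoffs (default 6, 8, 10, 12, 14).
#' @param config Base [train_config()]; its `C` is overridden per run.
#' @param variant Pooling variant to sweep (default `"ramil"`).
#' @param encoder Optional encoder for image bags.
#' @return A `ramil_sweep` tibble, one row per `C`, with all metrics; per-run
#'   probabilities are kept in the `probs` attribute.
#' @export
sweep_c <- function(train_bags, test_bags, c_values = c(6L, 8L, 10L, 12L, 14L),
                    config = train_config(), variant = "ramil", encoder = NULL) {
  runs <- lapply(c_values, function(cv) {
    cfg <- config
    cfg$C <- as.integer(cv)
    model <- train_mil(train_bags, cfg, variant, encoder)
    ev <- evaluate_model(model, test_bags, seed = config$seed)
    list(row = dplyr::bind_cols(tibble::tibble(C = cv), eval_row(ev)),
         probs = ev$probs)
  })
  out <- dplyr::bind_rows(lapply(runs, `[[`, "row"))
  attr(out, "probs") <- stats::setNames(lapply(runs, `[[`, "probs"),
                                        paste0("C", c_values))
  class(out) <- c("ramil_sweep", class(out))
  out
}

# per-bag probability assigned to the bag's true class; the samples fed to
# the Mann-Whitney comparison between models
correct_class_prob <- function(probs, labels) {
  ifelse(labels == 1, probs, 1 - probs)
}

#' Compare pooling variants on identical splits
#'
#' Trains every requested variant with the same seed (hence identical
#' train/validation splits and comparable initialization), evaluates each on
#' the same test bags, and tests each baseline against the ranking-attention
#' model with a two-sided Mann-Whitney U test on the per-bag probabilities
#' assigned to the true class.
#'
#' @param train_bags,test_bags Bag tibbles.
#' @param variants Pooling variants to compare (first is the reference).
#' @param config [train_config()] shared across variants.
#' @param encoder Optional encoder for image bags.
#' @return A `ramil_comparison` tibble, one row per variant, with metrics and
#'   `p_value` versus the reference; per-variant probabilities in the
#'   `probs` attribute.
#' @export
compare_poolings <- function(train_bags, test_bags,
                             variants = c("ramil", "attention", "gated",
                                          "mean", "max"),
                             config = train_config(), encoder = NULL) {
  runs <- lapply(variants, function(v) {
    model <- train_mil(train_bags, config, v, encoder)
    ev <- evaluate_model(model, test_bags, seed = config$seed)
    list(row = dplyr::bind_cols(tibble::tibble(variant = v), eval_row(ev)),
         probs = ev$probs)
  })
  names(runs) <- variants
  ref <- correct_class_prob(runs[[1]]$probs$prob, runs[[1]]$probs$label)
  p_values <- vapply(runs, function(r) {
    mann_whitney_u(ref, correct_class_prob(r$probs$prob, r$probs$label))$p_value
  }, numeric(1))
  out <- dplyr::bind_rows(lapply(runs, `[[`, "row"))
  out$p_value <- unname(p_values)
  attr(out, "probs") <- lapply(runs, `[[`, "probs")
  class(out) <- c("ramil_comparison", class(out))
  out
}
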