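#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training history curves
#'
#' Per-epoch training loss and validation AUC, with the restored best epoch
#' marked.
#'
#' @param object A `ramil_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ramil_model
#' @export
autoplot.ramil_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_auc"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("%s pooling: best val AUC %.3f at epoch %d",
                                  object$variant, object$best_val_auc,
                                  object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' ROC curve of an evaluation
#'
#' @param object A `ramil_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ramil_eval
#' @export
autoplot.ramil_eval <- function(object, ...) {
  pts <- roc_points(object$probs$prob, object$probs$label)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)", object$auc,
                                  object$auc_ci["lower"], object$auc_ci["upper"])) +
    ggplot2::theme_minimal()
}

#' Metric curves across the ranking cutoff sweep
#'
#' @param object A `ramil_sweep`.
#' @param metrics Which metric columns to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ramil_sweep
#' @export
autoplot.ramil_sweep <- function(object, metrics = c("auc", "acc", "f1"), ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$C, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ranking cutoff C", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Attention profile of one bag
#'
#' Bars of the per-slice attention scores in acquisition order, selected
#' slices filled.
#'
#' @param object A `ramil_attribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ramil_attribution
#' @export
autoplot.ramil_attribution <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$score,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "slice (acquisition order)", y = "attention score",
                  fill = "selected") +
    ggplot2::theme_minimal()
}
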