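# Model explanation: the per-slice attention scores are the contributions of
# slices to the bag prediction, and Grad-CAM on the encoder's last
# convolutional block localizes the image regions driving the bag logit.

#' Rank the slices of one bag by attention
#'
#' Runs the model forward on one bag and lists its slices by descending
#' attention score (ties by slice number), flagging the `min(C, K)` selected
#' slices. Scores are the raw softmax outputs and sum to 1; slice numbers are
#' 1-based acquisition indices.
#'
#' @param model A `ramil_model` with an attention-based variant.
#' @param bag One-row bag tibble (features or slices).
#' @return A `ramil_attribution` tibble: `slice`, `score`, `rank`,
#'   `selected`.
#' @export
rank_slices <- function(model, bag) {
  stopifnot(nrow(bag) == 1)
  if (!model$variant %in% c("ramil", "attention", "gated")) {
    abort_ramil("slice ranking needs an attention-based variant.")
  }
  H <- model_features(bag, model$encoder)[[1]]
  fwd <- mil_forward(H, model$params, model$head, model$config$C, model$variant)
  a <- fwd$scores
  ord <- order(-a, seq_along(a))
  selected <- if (!is.null(fwd$selection)) {
    seq_along(a) %in% fwd$selection$indices
  } else {
    rank_sel <- ord[seq_len(min(model$config$C, length(a)))]
    seq_along(a) %in% rank_sel
  }
  out <- tibble::tibble(
    slice = ord,
    score = a[ord],
    rank = seq_along(ord),
    selected = selected[ord],
    prob = fwd$prob
  )
  class(out) <- c("ramil_attribution", class(out))
  out
}

# d(bag logit) / d(embedding h_k) for every slice of a bag; the gradient
# flows through the selected scores' weights and, via the softmax
# denominator, through all logits
bag_logit_grad <- function(model, H) {
  fwd <- mil_forward(H, model$params, model$head, model$config$C, model$variant)
  g <- mil_backward(H, model$params, model$head, fwd, dlogit = 1,
                    variant = model$variant)
  list(fwd = fwd, dH = g$dH)
}

#' Grad-CAM heatmap for one slice
#'
#' Backpropagates the bag logit (pre-sigmoid) through the full bag forward —
#' so the attention weighting participates in the gradient — down to the
#' encoder's last convolutional activations. Channel weights are the spatial
#' means of the gradient; the map is the ReLU of the weighted activation sum,
#' bilinearly upsampled to the slice size and max-normalized for display.
#' A slice with no gradient path (e.g. outside the top-C selection) yields a
#' zero map with a warning.
#'
#' @param model A `ramil_model` whose encoder is convolutional.
#' @param bag One-row bag tibble with a `slices` column.
#' @param slice_index Which slice to explain (1-based).
#' @param feature_stats Optional `list(mean, sd)` if the model was trained on
#'   features standardized with [standardize_features()]; the forward and the
#'   gradient are chained through the same transform.
#' @param encoder The convolutional encoder to attribute through; defaults to
#'   the model's own. Pass it explicitly when the model was trained on
#'   features precomputed with a frozen encoder.
#' @return Heatmap matrix at slice resolution, values in `[0, 1]`.
#' @export
grad_cam <- function(model, bag, slice_index, feature_stats = NULL,
                     encoder = NULL) {
  stopifnot(nrow(bag) == 1)
  enc <- encoder %||% model$encoder
  if (is.null(enc) || enc$spec$name != "conv") {
    abort_ramil("Grad-CAM requires a convolutional encoder.")
  }
  sl <- slice_list(bag$slices[[1]])
  if (slice_index < 1 || slice_index > length(sl)) {
    abort_ramil("`slice_index` out of range.")
  }
  caches <- lapply(sl, function(x) encoder_forward(enc, x, keep_cache = TRUE))
  H <- do.call(rbind, lapply(caches, `[[`, "h"))
  if (!is.null(feature_stats)) {
    H <- sweep(sweep(H, 2, feature_stats$mean), 2, feature_stats$sd, "/")
  }
  bg <- bag_logit_grad(model, H)
  dh <- bg$dH[slice_index, ]
  if (!is.null(feature_stats)) dh <- dh / feature_stats$sd
  cache <- caches[[slice_index]]$cache
  A2 <- cache$c2$out                       # oh x ow x ch activations
  d2 <- dim(A2)
  # channel weights: spatial mean of the logit gradient at the activations
  dA2 <- conv_activation_grad(enc, cache, dh)
  alpha <- apply(dA2, 3, mean)
  cam <- matrix(0, d2[1], d2[2])
  for (c in seq_len(d2[3])) cam <- cam + alpha[c] * A2[, , c]
  cam <- pmax(cam, 0)
  if (all(dh == 0)) {
    warning("zero gradient everywhere; returning a zero map.", call. = FALSE)
    return(matrix(0, nrow(sl[[slice_index]]), ncol(sl[[slice_index]])))
  }
  if (max(cam) == 0) {
    return(matrix(0, nrow(sl[[slice_index]]), ncol(sl[[slice_index]])))
  }
  up <- EBImage::resize(EBImage::Image(cam), w = nrow(sl[[slice_index]]),
                        h = ncol(sl[[slice_index]]))
  m <- EBImage::imageData(up)
  m <- pmax(m, 0)
  m / max(m)
}

#' Full slice attribution for one bag
#'
#' Attention ranking plus (for convolutional encoders) per-slice Grad-CAM
#' heatmaps.
#'
#' @param model A `ramil_model`.
#' @param bag One-row bag tibble.
#' @param heatmaps Compute Grad-CAM maps for every slice.
#' @param feature_stats Optional standardization statistics (see
#'   [grad_cam()]).
#' @param encoder Optional explicit convolutional encoder (see [grad_cam()]).
#' @return A `ramil_attribution` tibble; heatmaps, when computed, are stored
#'   in the `heatmaps` attribute (list indexed by slice number).
#' @export
explain_bag <- function(model, bag, heatmaps = FALSE, feature_stats = NULL,
                        encoder = NULL) {
  attribution <- rank_slices(model, bag)
  if (heatmaps) {
    K <- nrow(attribution)
    maps <- lapply(seq_len(K), function(k) {
      grad_cam(model, bag, k, feature_stats = feature_stats, encoder = encoder)
    })
    attr(attribution, "heatmaps") <- maps
  }
  attribution
}

overlay_rgb <- function(slice, heatmap) {
  base <- clamp(slice, 0, 1)
  out <- array(0, c(dim(base), 3))
  out[, , 1] <- clamp(base + 0.7 * heatmap, 0, 1)   # heat in red
  out[, , 2] <- base * (1 - 0.5 * heatmap)
  out[, , 3] <- base * (1 - 0.5 * heatmap)
  out
}

#' Export overlay panels for one bag
#'
#' Writes one PNG per slice (grayscale slice with its heatmap in red),
#' filenames carrying rank and attention score, plus a `summary.png` panel
#' juxtaposing the highest- and lowest-scored slices.
#'
#' @param bag One-row bag tibble with `slices`.
#' @param attribution An [explain_bag()] result with heatmaps.
#' @param out_dir Output directory.
#' @param n_panel Slices from each extreme in the summary panel.
#' @return Written file paths, invisibly.
#' @export
export_overlays <- function(bag, attribution, out_dir, n_panel = 3L) {
  maps <- attr(attribution, "heatmaps")
  if (is.null(maps)) abort_ramil("attribution has no heatmaps; run explain_bag(heatmaps = TRUE).")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sl <- slice_list(bag$slices[[1]])
  paths <- character(nrow(attribution))
  for (i in seq_len(nrow(attribution))) {
    k <- attribution$slice[i]
    paths[i] <- file.path(out_dir, sprintf("rank%02d_slice%02d_score%.4f.png",
                                           attribution$rank[i], k,
                                           attribution$score[i]))
    png::writePNG(overlay_rgb(sl[[k]], maps[[k]]), paths[i])
  }
  n_panel <- min(n_panel, floor(nrow(attribution) / 2))
  top <- attribution$slice[seq_len(n_panel)]
  bottom <- rev(attribution$slice)[seq_len(n_panel)]
  tiles <- lapply(c(top, bottom), function(k) overlay_rgb(sl[[k]], maps[[k]]))
  h <- nrow(tiles[[1]])
  w <- ncol(tiles[[1]])
  panel <- array(0, c(2 * h, n_panel * w, 3))
  for (j in seq_len(n_panel)) {
    panel[seq_len(h), (j - 1) * w + seq_len(w), ] <- tiles[[j]]
    panel[h + seq_len(h), (j - 1) * w + seq_len(w), ] <- tiles[[n_panel + j]]
  }
  summary_path <- file.path(out_dir, "summary.png")
  png::writePNG(panel, summary_path)
  invisible(c(paths, summary_path))
}
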