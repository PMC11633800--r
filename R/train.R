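# Optimization loop: Adam over attention + head (+ encoder when trainable),
# one bag per step (bags have variable K), class-weighted cross entropy,
# early stopping on validation AUC with best-checkpoint restoration.

#' Augmentation specification
#'
#' Random horizontal/vertical flips and rotation, each applied independently
#' with its probability; the rotation angle is uniform in `rotate_range`
#' (degrees). Within one optimization step the same draw is applied to every
#' slice of the bag, preserving inter-slice anatomical consistency.
#'
#' @param hflip_p,vflip_p Flip probabilities.
#' @param rotate_p Rotation probability.
#' @param rotate_range Length-2 angle range in degrees.
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(hflip_p = 0.5, vflip_p = 0.5,
                         rotate_p = 0.2, rotate_range = c(0, 40)) {
  stopifnot(length(rotate_range) == 2, rotate_range[1] <= rotate_range[2])
  structure(list(hflip_p = hflip_p, vflip_p = vflip_p, rotate_p = rotate_p,
                 rotate_range = rotate_range), class = "augment_spec")
}

# draw one augmentation plan from the current RNG stream
draw_augment <- function(spec) {
  list(
    hflip = stats::runif(1) < spec$hflip_p,
    vflip = stats::runif(1) < spec$vflip_p,
    angle = if (stats::runif(1) < spec$rotate_p) {
      stats::runif(1, spec$rotate_range[1], spec$rotate_range[2])
    } else 0
  )
}

apply_augment <- function(slice, plan) {
  if (plan$hflip) slice <- slice[, rev(seq_len(ncol(slice))), drop = FALSE]
  if (plan$vflip) slice <- slice[rev(seq_len(nrow(slice))), , drop = FALSE]
  if (plan$angle != 0) {
    rot <- EBImage::rotate(EBImage::Image(slice), plan$angle, bg.col = 0)
    slice <- center_crop(EBImage::imageData(rot), nrow(slice))
  }
  slice
}

#' Augment one slice
#'
#' @param slice 2D matrix.
#' @param spec An [augment_spec()].
#' @return Transformed slice (same size; rotation fills with zeros and
#'   re-crops to the original frame).
#' @export
augment_slice <- function(slice, spec = augment_spec()) {
  apply_augment(slice, draw_augment(spec))
}

#' Training configuration
#'
#' Defaults follow the protocol the model was developed with: Adam with
#' learning rate `2e-5`, `beta1 = 0.9`, `beta2 = 0.999`, weight decay `1e-4`,
#' batch size 1, at most 200 epochs with patience 20 on validation AUC, a 10%
#' stratified validation split, ranking cutoff `C = 10` and attention width
#' `D = 128`. The small learning rate suits fine-tuning a pretrained
#' backbone; training lightweight encoders from scratch typically wants a
#' larger rate (see the methods vignette).
#'
#' @param learning_rate,adam_beta1,adam_beta2,weight_decay Adam settings.
#' @param batch_size Bags per optimization step (1: bags have variable K).
#' @param max_epochs,patience Epoch budget and early-stopping patience
#'   (`patience < max_epochs`).
#' @param val_fraction Fraction of training subjects held out for validation.
#' @param C Ranking cutoff.
#' @param D Attention hidden width.
#' @param seed Master seed; all RNG streams (split, init, shuffling,
#'   augmentation) derive from it.
#' @param augment An [augment_spec()] (applied to image bags only).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-5,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         weight_decay = 1e-4,
                         batch_size = 1L,
                         max_epochs = 200L, patience = 20L,
                         val_fraction = 0.10,
                         C = 10L, D = 128L,
                         seed = 1L,
                         augment = augment_spec()) {
  if (patience >= max_epochs) abort_ramil("`patience` must be < `max_epochs`.")
  if (val_fraction <= 0 || val_fraction >= 1) {
    abort_ramil("`val_fraction` must be in (0, 1).")
  }
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, C = as.integer(C),
                 D = as.integer(D), seed = as.integer(seed),
                 augment = augment),
            class = "train_config")
}

#' Training configuration for from-scratch synthetic experiments
#'
#' The default [train_config()] carries fine-tuning settings appropriate for
#' a pretrained backbone. Training the attention network, head and a
#' lightweight encoder from random initialization is a different optimization
#' regime; these settings (Adam at `3e-3`, weight decay `1e-2`, gradient
#' accumulation over 8 bags) are the package's standing choice for the
#' synthetic benchmarks. See the methods vignette for the rationale.
#'
#' @param seed Master seed.
#' @param ... Overrides passed on to [train_config()].
#' @return A `train_config`.
#' @export
synthetic_train_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(learning_rate = 3e-3, weight_decay = 1e-2, batch_size = 8L,
         max_epochs = 200L, patience = 20L, seed = seed),
    list(...))
  do.call(train_config, args)
}

#' End-to-end trainable projection for feature bags
#'
#' An identity-initialized linear encoder applied to already-extracted
#' feature vectors, mirroring the end-to-end training of the full image
#' pipeline at feature scale: the projection receives gradients from both the
#' attention network and the classification head, letting the attention
#' scores ride on the head's better-estimated signal direction.
#'
#' @param L Feature dimension (input and output).
#' @param seed Initialization seed.
#' @return A `ramil_encoder`.
#' @export
feature_projection_encoder <- function(L, seed = 1L) {
  build_encoder(encoder_spec("linear", output_dim = L, input_dim = L,
                             init = "identity", trainable = TRUE, seed = seed))
}

#' Hold out a validation split, stratified by label
#'
#' Patient-level and stratified: the validation set size is
#' `round(n * val_fraction)` with at least one bag per class, and the class
#' ratio is preserved to within one bag. Deterministic per seed.
#'
#' @param bags Bag tibble.
#' @param val_fraction Fraction to hold out.
#' @param seed Seed.
#' @return List with `train` and `val` bag tibbles (disjoint).
#' @export
split_validation <- function(bags, val_fraction = 0.10, seed = 1L) {
  n <- nrow(bags)
  pos <- which(bags$label == 1)
  neg <- which(bags$label == 0)
  if (length(pos) == 0 || length(neg) == 0) {
    abort_ramil("both classes are required to split.", "ramil_single_class")
  }
  n_val <- round(n * val_fraction)
  n_val_pos <- min(max(1L, round(n_val * length(pos) / n)), length(pos) - 1L)
  n_val_neg <- min(max(1L, n_val - n_val_pos), length(neg) - 1L)
  with_seed(seed, {
    val_idx <- c(sample(pos, n_val_pos), sample(neg, n_val_neg))
  })
  list(train = bags[-val_idx, ], val = bags[val_idx, ])
}

#' Stratified k-fold partition
#'
#' Folds are disjoint, exhaustive, and hold the same proportion of positive
#' bags (positive counts differ by at most one across folds). Deterministic
#' per seed.
#'
#' @param bags Bag tibble.
#' @param k Number of folds.
#' @param seed Seed.
#' @return List of `k` integer vectors of row indices (the test fold).
#' @export
stratified_kfold <- function(bags, k = 5L, seed = 1L) {
  with_seed(seed, {
    folds <- replicate(k, integer(0), simplify = FALSE)
    for (cls in c(1, 0)) {
      idx <- sample(which(bags$label == cls))
      for (i in seq_along(idx)) {
        f <- ((i - 1L) %% k) + 1L
        folds[[f]] <- c(folds[[f]], idx[i])
      }
    }
    lapply(folds, sort)
  })
}

# flat parameter bookkeeping for Adam -------------------------------------

init_adam <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, t, cfg) {
  lr <- cfg$learning_rate; b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + cfg$weight_decay * params[[nm]]   # decoupled-from-loss L2, Adam-style
    state[[nm]]$m <- b1 * state[[nm]]$m + (1 - b1) * g
    state[[nm]]$v <- b2 * state[[nm]]$v + (1 - b2) * g^2
    mhat <- state[[nm]]$m / (1 - b1^t)
    vhat <- state[[nm]]$v / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
  }
  list(params = params, state = state)
}

# early-stopping bookkeeping: strict improvement over the best seen
update_early_stop <- function(state, auc, epoch) {
  if (is.null(state)) state <- list(best = -Inf, best_epoch = 0L, stale = 0L)
  if (auc > state$best) {
    state$best <- auc
    state$best_epoch <- epoch
    state$stale <- 0L
  } else {
    state$stale <- state$stale + 1L
  }
  state
}

bag_features <- function(bags) {
  if (!is.null(bags$features)) return(bags$features)
  abort_ramil("bags carry no `features`; encode slices first (see encode_bags()).")
}

# feature matrices as the pooling layer sees them: raw feature bags pass
# through a (possibly trainable) linear projection when one is attached;
# image bags are encoded slice by slice
model_features <- function(bags, encoder) {
  if (!is.null(bags$features)) {
    if (!is.null(encoder) && encoder$spec$name == "linear" &&
        !is.null(encoder$spec$input_dim)) {
      Wt <- t(encoder$params$W)
      lapply(bags$features, function(H) H %*% Wt)
    } else {
      bags$features
    }
  } else {
    lapply(bags$slices, encode_bag, encoder = encoder)
  }
}

predict_probs <- function(bags, params, head, C, variant, encoder = NULL) {
  vapply(model_features(bags, encoder), function(H) {
    mil_forward(H, params, head, C, variant)$prob
  }, numeric(1))
}

#' Train a ranking-attention MIL model
#'
#' Optimizes the attention network and classification head (and the encoder,
#' when it is trainable and the bags carry raw slices) jointly with Adam, one
#' bag per step, under the class-weighted cross entropy. Validation AUC is
#' tracked each epoch; training stops once it has not strictly improved for
#' `patience` consecutive epochs (or at `max_epochs`) and the weights of the
#' best-AUC epoch are restored.
#'
#' @param bags Training bag tibble (both classes present). Feature bags use
#'   the `features` list-column directly; image bags (a `slices` column) are
#'   encoded through `encoder`.
#' @param config A [train_config()].
#' @param variant Pooling variant: `"ramil"`, `"attention"`, `"gated"`,
#'   `"mean"` or `"max"`.
#' @param encoder Optional `ramil_encoder` for image bags. A frozen encoder
#'   has its features computed once up front; a trainable one is updated
#'   end-to-end.
#' @param val_bags Optional explicit validation bags; by default a stratified
#'   `val_fraction` split is carved out of `bags`.
#' @return A `ramil_model` with elements `params`, `head`, `encoder`,
#'   `config`, `variant`, `loss_spec`, `history` (tibble of epoch, train
#'   loss, validation AUC) and `best_epoch`.
#' @export
train_mil <- function(bags, config = train_config(),
                      variant = c("ramil", "attention", "gated", "mean", "max"),
                      encoder = NULL, val_bags = NULL) {
  variant <- match.arg(variant)
  if (length(unique(bags$label)) < 2) {
    abort_ramil("training bags must contain both classes.", "ramil_single_class")
  }
  image_mode <- is.null(bags$features)
  if (image_mode && is.null(encoder)) {
    abort_ramil("image bags require an `encoder`.")
  }

  if (is.null(val_bags)) {
    sp <- split_validation(bags, config$val_fraction, child_seed(config$seed, 1))
    train_bags <- sp$train
    val_bags <- sp$val
  } else {
    train_bags <- bags
  }

  # frozen encoder on images: encode once up front
  if (image_mode && !isTRUE(encoder$spec$trainable)) {
    train_bags <- encode_bags(train_bags, encoder)
    if (is.null(val_bags$features)) val_bags <- encode_bags(val_bags, encoder)
    image_mode <- FALSE
  } else if (image_mode && is.null(val_bags$features)) {
    val_bags <- encode_bags(val_bags, encoder)
  }
  # trainable linear projection applied to already-extracted feature bags
  feature_proj <- !image_mode && !is.null(encoder) &&
    encoder$spec$name == "linear" && !is.null(encoder$spec$input_dim) &&
    isTRUE(encoder$spec$trainable)
  encoder_trainable <- image_mode || feature_proj

  L <- if (!is.null(encoder)) encoder$spec$output_dim else ncol(train_bags$features[[1]])
  lspec <- loss_spec(sum(train_bags$label == 1), sum(train_bags$label == 0))
  params <- attention_params(L, config$D, gated = variant == "gated",
                             seed = child_seed(config$seed, 2))
  # zero head start: the first updates are driven by the bag embeddings
  # alone, so the attention network never chases a random initial readout
  head <- list(weight = numeric(L), bias = 0)

  astate <- init_adam(params)
  hstate <- init_adam(head)
  estate <- if (encoder_trainable) init_adam(encoder$params) else NULL

  n_train <- nrow(train_bags)
  labels <- train_bags$label
  feats <- if (!image_mode) train_bags$features
  history <- vector("list", config$max_epochs)
  es <- NULL
  best <- list(params = params, head = head,
               enc = if (encoder_trainable) encoder$params)
  t_step <- 0L
  bsz <- max(1L, config$batch_size)

  with_seed(child_seed(config$seed, 4), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_train)
      epoch_loss <- 0
      i <- 1L
      while (i <= n_train) {
        batch <- ord[i:min(i + bsz - 1L, n_train)]
        acc <- NULL
        eg <- NULL
        for (b in batch) {
          caches <- NULL
          if (image_mode) {
            plan <- draw_augment(config$augment)
            sl <- slice_list(train_bags$slices[[b]])
            sl <- lapply(sl, apply_augment, plan = plan)
            caches <- lapply(sl, function(x) encoder_forward(encoder, x, keep_cache = TRUE))
            H <- do.call(rbind, lapply(caches, `[[`, "h"))
          } else if (feature_proj) {
            H0 <- feats[[b]]
            H <- H0 %*% t(encoder$params$W)
          } else {
            H <- feats[[b]]
          }
          fwd <- mil_forward(H, params, head, config$C, variant)
          q <- clamp(fwd$prob, 1e-7, 1 - 1e-7)
          y <- labels[b]
          loss_b <- if (y == 1) -lspec$beta_P * log(q) else -lspec$beta_N * log(1 - q)
          if (!is.finite(loss_b)) {
            abort_ramil(sprintf(
              "non-finite loss at epoch %d (bag %s, prob %g); aborting.",
              epoch, train_bags$patient_id[b], fwd$prob))
          }
          epoch_loss <- epoch_loss + loss_b
          # dLoss/dlogit of the sigmoid head
          dlogit <- if (y == 1) -lspec$beta_P * (1 - q) else lspec$beta_N * q
          g <- mil_backward(H, params, head, fwd, dlogit, variant)
          if (image_mode) {
            for (k in seq_len(nrow(H))) {
              gk <- encoder_backward(encoder, caches[[k]]$cache, g$dH[k, ])
              eg <- if (is.null(eg)) gk else Map(`+`, eg, gk)
            }
          } else if (feature_proj) {
            gk <- list(W = crossprod(g$dH, H0))
            eg <- if (is.null(eg)) gk else Map(`+`, eg, gk)
          }
          g$dH <- NULL
          acc <- if (is.null(acc)) g else Map(`+`, acc, g)
        }
        t_step <- t_step + 1L
        up <- adam_step(params,
                        acc[intersect(names(params), names(acc))],
                        astate, t_step, config)
        params <- up$params; astate <- up$state
        uph <- adam_step(head, list(weight = acc$head_weight, bias = acc$head_bias),
                         hstate, t_step, config)
        head <- uph$params; hstate <- uph$state
        if (encoder_trainable) {
          upe <- adam_step(encoder$params, eg, estate, t_step, config)
          encoder$params <- upe$params; estate <- upe$state
        }
        i <- i + bsz
      }
      val_probs <- predict_probs(val_bags, params, head, config$C, variant, encoder)
      val_auc <- auc_rank(val_probs, val_bags$label)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = epoch_loss / n_train, val_auc = val_auc)
      es <- update_early_stop(es, val_auc, epoch)
      if (es$best_epoch == epoch) {
        best <- list(params = params, head = head,
                     enc = if (encoder_trainable) encoder$params)
      }
      if (es$stale >= config$patience) break
    }
  })

  if (!is.null(best$enc)) encoder$params <- best$enc
  structure(
    list(params = best$params, head = best$head, encoder = encoder,
         config = config, variant = variant, loss_spec = lspec,
         history = dplyr::bind_rows(history),
         best_epoch = es$best_epoch, best_val_auc = es$best,
         L = L, n_train = n_train),
    class = "ramil_model"
  )
}

#' @export
print.ramil_model <- function(x, ...) {
  cat(sprintf("<ramil_model> %s pooling, L = %d, D = %d, C = %d\n",
              x$variant, x$L, x$config$D, x$config$C))
  cat(sprintf("  trained %d epochs on %d bags; best val AUC %.3f at epoch %d\n",
              nrow(x$history), x$n_train, x$best_val_auc, x$best_epoch))
  invisible(x)
}

#' Predict bag probabilities
#'
#' @param object A `ramil_model`.
#' @param bags Bag tibble (feature or image bags).
#' @param ... Unused.
#' @return A tibble with `patient_id`, `label` (if present) and `prob`.
#' @export
predict.ramil_model <- function(object, bags, ...) {
  probs <- predict_probs(bags, object$params, object$head, object$config$C,
                         object$variant, object$encoder)
  out <- tibble::tibble(patient_id = bags$patient_id, prob = probs)
  if (!is.null(bags$label)) out$label <- bags$label
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted MIL model: one row per parameter group
#'
#' @param x A `ramil_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `n_parameters`, `l2_norm`.
#' @method tidy ramil_model
#' @export
tidy.ramil_model <- function(x, ...) {
  groups <- c(x$params, list(head_weight = x$head$weight, head_bias = x$head$bias))
  tibble::tibble(
    term = names(groups),
    n_parameters = vapply(groups, length, integer(1)),
    l2_norm = vapply(groups, function(p) sqrt(sum(p^2)), numeric(1))
  )
}

#' One-row training summary
#'
#' @param x A `ramil_model`.
#' @param ... Unused.
#' @return Tibble with variant, sizes, epochs run and best validation AUC.
#' @method glance ramil_model
#' @export
glance.ramil_model <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, L = x$L, D = x$config$D, C = x$config$C,
    n_train = x$n_train, epochs = nrow(x$history),
    best_epoch = x$best_epoch, best_val_auc = x$best_val_auc,
    beta_P = x$loss_spec$beta_P, beta_N = x$loss_spec$beta_N
  )
}
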