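# Per-slice feature extraction: the encoder contract maps any slice to a
# length-L vector, deterministically in evaluation mode. The package ships two
# lightweight encoders implemented natively (a flatten-then-project linear
# encoder and a 2-conv-block CNN with global average pooling), plus a "custom"
# hook for user-supplied backbones. The CNN exposes its convolutional
# activations so Grad-CAM can attribute predictions to image regions.

#' Describe an encoder
#'
#' @param name `"linear"` (flatten-then-project), `"conv"` (2 conv blocks +
#'   projection), `"identity"` (features already extracted, e.g. synthetic
#'   feature bags), or `"custom"` (user function via `fn`).
#' @param output_dim Embedding length L (e.g. 1000 for a full-scale backbone;
#'   small values suit CPU-scale work).
#' @param pretrained Whether weights come from a pretrained checkpoint
#'   (informational; the shipped encoders initialize randomly).
#' @param trainable Train the encoder end-to-end. Freezing is the economical
#'   choice when the pooling head alone is being studied.
#' @param input_size Expected slice side length.
#' @param in_channels 1 for grayscale; 3 replicates a grayscale slice across
#'   channels for channel-expecting backbones.
#' @param input_dim Flattened input length for the linear encoder; defaults
#'   to `input_size^2 * in_channels`. Set it explicitly to project
#'   already-extracted feature vectors (e.g. `input_dim = L` for an
#'   end-to-end trainable projection on feature bags).
#' @param init `"identity"` or `"gaussian"` initialization (linear encoder).
#' @param seed Seed for weight initialization.
#' @param fn For `name = "custom"`: function mapping a 2D slice to a
#'   length-`output_dim` numeric vector.
#' @return An `encoder_spec` object.
#' @export
encoder_spec <- function(name = c("linear", "conv", "identity", "custom"),
                         output_dim = 16L,
                         pretrained = FALSE,
                         trainable = !identical(name, "conv"),
                         input_size = 224L,
                         in_channels = 1L,
                         input_dim = NULL,
                         init = c("identity", "gaussian"),
                         seed = 1L,
                         fn = NULL) {
  name <- match.arg(name)
  init <- match.arg(init)
  if (output_dim < 1) abort_ramil("`output_dim` must be >= 1.")
  if (name == "custom" && !is.function(fn)) {
    abort_ramil("custom encoders need `fn`.")
  }
  structure(
    list(name = name, output_dim = as.integer(output_dim),
         pretrained = isTRUE(pretrained), trainable = isTRUE(trainable),
         input_size = as.integer(input_size), in_channels = as.integer(in_channels),
         input_dim = if (!is.null(input_dim)) as.integer(input_dim),
         init = init, seed = as.integer(seed), fn = fn),
    class = "encoder_spec"
  )
}

# cached im2col index matrices, keyed by geometry
.im2col_cache <- new.env(parent = emptyenv())

im2col_indices <- function(h, w, ch, k, stride, pad) {
  key <- paste(h, w, ch, k, stride, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  ph <- h + 2 * pad
  pw <- w + 2 * pad
  oh <- (ph - k) %/% stride + 1
  ow <- (pw - k) %/% stride + 1
  r0 <- rep(seq(1, by = stride, length.out = oh), times = ow)
  c0 <- rep(seq(1, by = stride, length.out = ow), each = oh)
  dr <- rep(rep(seq_len(k), times = k), times = ch)
  dc <- rep(rep(seq_len(k), each = k), times = ch)
  ci <- rep(seq_len(ch), each = k * k)
  rr <- outer(r0 - 1L, dr, "+")               # absolute row
  cc <- outer(c0 - 1L, dc, "+")               # absolute col
  idx <- rr + (cc - 1L) * ph +
    matrix((ci - 1L) * ph * pw, nrow(rr), ncol(rr), byrow = TRUE)
  out <- list(idx = idx, oh = oh, ow = ow, ph = ph, pw = pw, ch = ch, pad = pad)
  .im2col_cache[[key]] <- out
  out
}

pad_array <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

conv_forward <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  geo <- im2col_indices(d[1], d[2], d[3], k, stride, pad)
  xp <- pad_array(x, pad)
  xcol <- matrix(xp[geo$idx], nrow(geo$idx), ncol(geo$idx))
  z <- sweep(xcol %*% W, 2, b, "+")
  a <- pmax(z, 0)
  list(out = array(a, c(geo$oh, geo$ow, ncol(W))),
       xcol = xcol, mask = z > 0, geo = geo, in_dim = d)
}

conv_backward <- function(cache, dout, W, need_dx = TRUE) {
  geo <- cache$geo
  och <- ncol(W)
  dz <- matrix(dout, nrow(geo$idx), och) * cache$mask
  grads <- list(W = crossprod(cache$xcol, dz), b = colSums(dz))
  dx <- NULL
  if (need_dx) {
    dxcol <- dz %*% t(W)
    dxp <- numeric(geo$ph * geo$pw * geo$ch)
    for (j in seq_len(ncol(geo$idx))) {
      ij <- geo$idx[, j]
      dxp[ij] <- dxp[ij] + dxcol[, j]
    }
    dxp <- array(dxp, c(geo$ph, geo$pw, geo$ch))
    p <- geo$pad
    dx <- dxp[p + seq_len(cache$in_dim[1]), p + seq_len(cache$in_dim[2]), ,
              drop = FALSE]
  }
  list(grads = grads, dx = dx)
}

he_init <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
}

#' Build an encoder from its spec
#'
#' Weight initialization is deterministic given `spec$seed`; the encoders are
#' pure functions of their weights, so evaluation is deterministic by
#' construction.
#'
#' @param spec An [encoder_spec()].
#' @return A `ramil_encoder` object.
#' @export
build_encoder <- function(spec) {
  stopifnot(inherits(spec, "encoder_spec"))
  L <- spec$output_dim
  params <- with_seed(spec$seed, switch(
    spec$name,
    identity = list(),
    custom = list(),
    linear = {
      P <- spec$input_dim %||% (spec$input_size^2 * spec$in_channels)
      W <- if (spec$init == "identity") {
        W0 <- matrix(0, L, P)
        diag(W0[seq_len(min(L, P)), seq_len(min(L, P))]) <- 1
        W0
      } else {
        matrix(stats::rnorm(L * P, sd = 1 / sqrt(P)), L, P)
      }
      list(W = W)
    },
    conv = {
      ch1 <- 8L; ch2 <- 16L
      # projection reads the concatenated mean + max spatial pool of the
      # last conv block: the max half keeps localized activations visible
      list(
        W1 = he_init(25L * spec$in_channels, ch1), b1 = numeric(ch1),
        W2 = he_init(9L * ch1, ch2), b2 = numeric(ch2),
        P = matrix(stats::rnorm(L * 2L * ch2, sd = 1 / sqrt(2 * ch2)), L, 2L * ch2),
        bL = numeric(L)
      )
    }
  ))
  structure(list(spec = spec, params = params), class = "ramil_encoder")
}

#' @export
print.ramil_encoder <- function(x, ...) {
  cat(sprintf("<ramil_encoder> %s, L = %d, %s\n", x$spec$name,
              x$spec$output_dim,
              if (x$spec$trainable) "trainable" else "frozen"))
  invisible(x)
}

as_channels <- function(x, in_channels) {
  if (is.numeric(x) && is.null(dim(x))) return(x)  # plain feature vector
  if (is.matrix(x)) {
    if (in_channels == 1L) {
      array(x, c(dim(x), 1L))
    } else {
      # grayscale replicated across channels for channel-expecting backbones
      array(rep(x, in_channels), c(dim(x), in_channels))
    }
  } else x
}

# forward one slice; with keep_cache = TRUE returns everything backward and
# Grad-CAM need
encoder_forward <- function(enc, x, keep_cache = FALSE) {
  spec <- enc$spec
  p <- enc$params
  switch(
    spec$name,
    identity = list(h = as.numeric(x), cache = NULL),
    custom = list(h = as.numeric(spec$fn(x)), cache = NULL),
    linear = {
      v <- as.numeric(as_channels(x, spec$in_channels))
      list(h = as.numeric(p$W %*% v), cache = if (keep_cache) list(x = v) else NULL)
    },
    conv = {
      x3 <- as_channels(x, spec$in_channels)
      c1 <- conv_forward(x3, p$W1, p$b1, k = 5L, stride = 4L, pad = 2L)
      c2 <- conv_forward(c1$out, p$W2, p$b2, k = 3L, stride = 2L, pad = 1L)
      d2 <- dim(c2$out)
      flat <- matrix(c2$out, d2[1] * d2[2], d2[3])
      gap <- colMeans(flat)
      amax <- max.col(t(flat), ties.method = "first")
      gmp <- flat[cbind(amax, seq_len(d2[3]))]
      pooled <- c(gap, gmp)
      h <- as.numeric(p$P %*% pooled + p$bL)
      list(h = h,
           cache = if (keep_cache) {
             list(c1 = c1, c2 = c2, pooled = pooled, amax = amax, d2 = d2)
           } else NULL)
    }
  )
}

# backward from dh (length L) to encoder parameter gradients
encoder_backward <- function(enc, cache, dh) {
  spec <- enc$spec
  p <- enc$params
  switch(
    spec$name,
    linear = list(W = tcrossprod(dh, cache$x)),
    conv = {
      dA2 <- conv_activation_grad(enc, cache, dh)
      b2 <- conv_backward(cache$c2, dA2, p$W2, need_dx = TRUE)
      b1 <- conv_backward(cache$c1, b2$dx, p$W1, need_dx = FALSE)
      list(W1 = b1$grads$W, b1 = b1$grads$b,
           W2 = b2$grads$W, b2 = b2$grads$b,
           P = tcrossprod(dh, cache$pooled), bL = dh)
    },
    list()
  )
}

# gradient of a scalar (reaching the embedding as dh) w.r.t. the last conv
# block's activations: the mean-pool half spreads uniformly, the max-pool
# half lands on each channel's argmax position
conv_activation_grad <- function(enc, cache, dh) {
  d2 <- cache$d2
  ch <- d2[3]
  npos <- d2[1] * d2[2]
  dpool <- as.numeric(crossprod(enc$params$P, dh))
  dgap <- dpool[seq_len(ch)]
  dgmp <- dpool[ch + seq_len(ch)]
  dflat <- matrix(rep(dgap / npos, each = npos), npos, ch)
  dflat[cbind(cache$amax, seq_len(ch))] <-
    dflat[cbind(cache$amax, seq_len(ch))] + dgmp
  array(dflat, d2)
}

slice_list <- function(slices) {
  if (is.array(slices) && length(dim(slices)) == 3) {
    lapply(seq_len(dim(slices)[3]), function(k) slices[, , k])
  } else if (is.list(slices)) {
    slices
  } else if (is.matrix(slices)) {
    list(slices)
  } else {
    abort_ramil("`slices` must be a 3D array, list of matrices, or a matrix.")
  }
}

#' Encode a bag of slices into a feature matrix
#'
#' Row `k` of the result is the embedding of slice `k`; slice order is
#' preserved. Identical slices map to identical rows.
#'
#' @param slices A `H x W x K` array, a list of `K` matrices, or a single
#'   matrix.
#' @param encoder A [build_encoder()] result.
#' @return A `K x L` numeric matrix.
#' @export
encode_bag <- function(slices, encoder) {
  sl <- slice_list(slices)
  L <- encoder$spec$output_dim
  H <- matrix(0, length(sl), L)
  for (k in seq_along(sl)) {
    h <- encoder_forward(encoder, sl[[k]])$h
    if (length(h) != L) {
      abort_ramil(sprintf("encoder returned length %d for slice %d (expected %d).",
                          length(h), k, L))
    }
    if (!all(is.finite(h))) {
      abort_ramil(sprintf("non-finite embedding for slice %d.", k))
    }
    H[k, ] <- h
  }
  H
}

#' Standardize bag features with training-set statistics
#'
#' Z-scores every feature column using the pooled per-feature mean and
#' standard deviation of the instances in `train_bags` (constant features are
#' left unscaled). Frozen-encoder features can sit far from zero at scales
#' that saturate the attention network's `tanh`; standardizing restores a
#' well-conditioned input, exactly as practitioners standardize extracted
#' features before a shallow model.
#'
#' @param bags Bag tibble(s) whose `features` to transform.
#' @param train_bags Bags supplying the statistics (default: `bags` itself).
#' @return `bags` with standardized `features`; the statistics are attached
#'   as attributes `feature_mean` and `feature_sd`.
#' @export
standardize_features <- function(bags, train_bags = bags) {
  all_h <- do.call(rbind, train_bags$features)
  mu <- colMeans(all_h)
  sdv <- apply(all_h, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  bags$features <- lapply(bags$features, function(H) {
    sweep(sweep(H, 2, mu), 2, sdv, "/")
  })
  attr(bags, "feature_mean") <- mu
  attr(bags, "feature_sd") <- sdv
  bags
}

#' Add a feature matrix column to a bag tibble
#'
#' Encodes the `slices` column of each bag with `encoder`, producing the
#' `features` column the pooling operators consume.
#'
#' @param bags Bag tibble with a `slices` list-column.
#' @param encoder A `ramil_encoder`.
#' @return `bags` with a `features` list-column of `K x L` matrices.
#' @export
encode_bags <- function(bags, encoder) {
  bags$features <- lapply(bags$slices, encode_bag, encoder = encoder)
  bags
}
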