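# Ranking-attention pooling core.
#
# Given a bag's feature matrix H (K x L), a small attention network scores
# every instance: a_k = softmax_k( w' tanh(V h_k') ). The C highest-scoring
# instances are selected (stable descending order, ties broken by the lower
# original index) and aggregated as z = sum_c a_c h_c with the selected
# scores left unrescaled, so the learned score distribution is preserved in
# the bag embedding. A single sigmoid unit on z yields the bag probability.
# Attention with C >= K recovers plain attention pooling exactly; mean, max
# and gated-attention pooling are provided as baselines.

#' Initialize attention parameters
#'
#' @param L Feature dimension of the instance embeddings.
#' @param D Hidden width of the attention network (default 128, common
#'   attention-pooling practice; the width is independent of bag size).
#' @param gated Also allocate the gating matrix `U` used by gated attention.
#' @param init_sd Standard deviation of the Gaussian initialization. The
#'   small default keeps initial scores near-uniform so that the selection
#'   starts neutral and the attention network follows the classification
#'   head's learned readout instead of locking onto its own random
#'   initialization (hard top-C selection cannot recover instances whose
#'   initial logits saturate low).
#' @param seed Seed for reproducible initialization.
#' @return List with `V` (D x L), `w` (length D) and optionally `U` (D x L).
#' @export
attention_params <- function(L, D = 128L, gated = FALSE, init_sd = 0.01,
                             seed = NULL) {
  with_seed(seed, {
    p <- list(V = matrix(stats::rnorm(D * L, sd = init_sd), D, L),
              w = stats::rnorm(D, sd = init_sd))
    if (gated) p$U <- matrix(stats::rnorm(D * L, sd = init_sd), D, L)
    p
  })
}

#' Compute normalized attention scores for a bag
#'
#' `a_k = exp(w' tanh(V h_k')) / sum_j exp(w' tanh(V h_j'))`, stabilized by
#' max-logit subtraction. Scores are nonnegative and sum to 1.
#'
#' @param H `K x L` feature matrix (K >= 1 rows).
#' @param params [attention_params()] with matching `L`.
#' @return Numeric vector of length K summing to 1.
#' @export
attention_scores <- function(H, params) {
  if (!is.matrix(H) || nrow(H) < 1) abort_ramil("`H` must have at least one row.")
  if (ncol(H) != ncol(params$V)) {
    abort_ramil(sprintf("feature dimension mismatch: H has L = %d, V expects %d.",
                        ncol(H), ncol(params$V)))
  }
  logits <- tanh(H %*% t(params$V)) %*% params$w
  e <- exp(logits - max(logits))
  as.numeric(e / sum(e))
}

gated_attention_scores <- function(H, params) {
  if (is.null(params$U)) abort_ramil("gated attention requires `U`.")
  t_ <- tanh(H %*% t(params$V))
  s_ <- sigmoid(H %*% t(params$U))
  logits <- (t_ * s_) %*% params$w
  e <- exp(logits - max(logits))
  as.numeric(e / sum(e))
}

#' Select the top-C scored instances
#'
#' Stable selection by descending score; ties are broken by the lower
#' original index. The selected scores are exact copies of the input scores —
#' never renormalized — and `C` is clamped to the bag size.
#'
#' @param a Attention score vector (length K).
#' @param H `K x L` feature matrix.
#' @param C Number of instances to keep (>= 1).
#' @return A `ramil_selection`: list with `indices` (1-based, length
#'   `min(C, K)`), `scores`, `features` and `C`.
#' @export
rank_select <- function(a, H, C) {
  if (C < 1) abort_ramil("`C` must be >= 1.", "ramil_invalid_config")
  if (length(a) != nrow(H)) abort_ramil("scores and features disagree on K.")
  ord <- order(-a, seq_along(a))   # stable: ties keep ascending index
  keep <- ord[seq_len(min(C, length(a)))]
  structure(
    list(indices = keep, scores = a[keep],
         features = H[keep, , drop = FALSE], C = as.integer(C)),
    class = "ramil_selection"
  )
}

#' Aggregate a ranked selection into the bag embedding
#'
#' `z = sum_c a_c h_c` over the selected instances, with the unrescaled
#' scores as weights.
#'
#' @param sel A [rank_select()] result.
#' @return Numeric vector of length L.
#' @export
aggregate_selection <- function(sel) {
  as.numeric(crossprod(sel$features, sel$scores))
}

#' Classification head: sigmoid of a single linear unit
#'
#' @param z Bag embedding (length L).
#' @param head List with `weight` (length L) and `bias` (scalar).
#' @return Probability in (0, 1).
#' @export
classify_embedding <- function(z, head) {
  sigmoid(sum(head$weight * z) + head$bias)
}

#' Column-wise mean pooling
#' @param H `K x L` feature matrix.
#' @return Length-L embedding.
#' @export
pool_mean <- function(H) colMeans(H)

#' Column-wise max pooling
#' @param H `K x L` feature matrix.
#' @return Length-L embedding.
#' @export
pool_max <- function(H) apply(H, 2, max)

#' Gated-attention pooling
#'
#' Adds a sigmoid gate to the attention logits:
#' `logit_k = w' ( tanh(V h_k') * sigm(U h_k') )`, softmax-normalized, then a
#' full-bag weighted sum.
#'
#' @param H `K x L` feature matrix.
#' @param params [attention_params()] built with `gated = TRUE`.
#' @return List with `scores` (length K) and `z` (length L).
#' @export
pool_gated_attention <- function(H, params) {
  a <- gated_attention_scores(H, params)
  list(scores = a, z = as.numeric(crossprod(H, a)))
}

#' Full forward pass through the pooling model
#'
#' Composition of attention scoring, top-C ranked selection, unrescaled
#' aggregation and the sigmoid head. The `"attention"` variant is the
#' `C >= K` special case of the same computation; `"gated"`, `"mean"` and
#' `"max"` are the baseline poolings (mean/max have no attention scores).
#'
#' @param H `K x L` feature matrix.
#' @param params Attention parameters (ignored by mean/max).
#' @param head Classification head.
#' @param C Ranking cutoff (clamped to K).
#' @param variant One of `"ramil"`, `"attention"`, `"gated"`, `"mean"`,
#'   `"max"`.
#' @return List with `prob`, `scores` (or `NULL`), `selection` (or `NULL`)
#'   and `z`.
#' @export
mil_forward <- function(H, params, head, C = 10L,
                        variant = c("ramil", "attention", "gated", "mean", "max")) {
  variant <- match.arg(variant)
  K <- nrow(H)
  if (variant %in% c("ramil", "attention")) {
    a <- attention_scores(H, params)
    sel <- rank_select(a, H, if (variant == "attention") K else C)
    z <- aggregate_selection(sel)
    list(prob = classify_embedding(z, head), scores = a, selection = sel, z = z)
  } else if (variant == "gated") {
    g <- pool_gated_attention(H, params)
    list(prob = classify_embedding(g$z, head), scores = g$scores,
         selection = NULL, z = g$z)
  } else {
    z <- if (variant == "mean") pool_mean(H) else pool_max(H)
    list(prob = classify_embedding(z, head), scores = NULL,
         selection = NULL, z = z)
  }
}

# Analytic backward pass for one bag. `dlogit` is dLoss/d(pre-sigmoid bag
# logit). Softmax is taken over all K instances and the hard top-C gather
# routes dz into the selected rows only; gradients still reach every
# instance's logit through the softmax denominator. Returns parameter
# gradients and dH for end-to-end encoder training.
mil_backward <- function(H, params, head, fwd, dlogit, variant = "ramil") {
  L <- ncol(H)
  K <- nrow(H)
  grads <- list(head_weight = dlogit * fwd$z, head_bias = dlogit)
  dz <- dlogit * head$weight
  if (variant %in% c("mean", "max")) {
    dH <- if (variant == "mean") {
      matrix(dz, K, L, byrow = TRUE) / K
    } else {
      dH0 <- matrix(0, K, L)
      amax <- max.col(t(H), ties.method = "first")   # first max per column
      dH0[cbind(amax, seq_len(L))] <- dz
      dH0
    }
    grads$dH <- dH
    return(grads)
  }
  a <- fwd$scores
  da <- numeric(K)
  if (variant == "gated") {
    da <- as.numeric(H %*% dz)
    dH_pool <- tcrossprod(a, dz)
  } else {
    sel <- fwd$selection
    da[sel$indices] <- as.numeric(sel$features %*% dz)
    dH_pool <- matrix(0, K, L)
    dH_pool[sel$indices, ] <- tcrossprod(sel$scores, dz)
  }
  # softmax backward over all K logits
  dg <- a * (da - sum(da * a))
  t_ <- tanh(H %*% t(params$V))          # K x D
  if (variant == "gated") {
    s_ <- sigmoid(H %*% t(params$U))
    grads$w <- as.numeric(crossprod(t_ * s_, dg))
    wt <- matrix(params$w, K, length(params$w), byrow = TRUE)
    dT <- (wt * s_) * dg                  # K x D, d logits / d t
    dS <- (wt * t_) * dg
    dpreV <- dT * (1 - t_^2)
    dpreU <- dS * s_ * (1 - s_)
    grads$V <- crossprod(dpreV, H)
    grads$U <- crossprod(dpreU, H)
    grads$dH <- dH_pool + dpreV %*% params$V + dpreU %*% params$U
  } else {
    grads$w <- as.numeric(crossprod(t_, dg))
    dpreV <- (matrix(params$w, K, length(params$w), byrow = TRUE) * (1 - t_^2)) * dg
    grads$V <- crossprod(dpreV, H)
    grads$dH <- dH_pool + dpreV %*% params$V
  }
  grads
}
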