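#' Class-weighting specification for the bag loss
#'
#' With `P` positive and `N` negative training bags, the positive term of the
#' cross entropy is weighted by `beta_P = N / (P + N)` and the negative term
#' by `beta_N = P / (P + N)`, so the minority class contributes more per bag.
#' If either class is absent both weights fall back to 1 (plain cross
#' entropy) with a warning.
#'
#' @param P,N Nonnegative counts of positive and negative training bags.
#' @return A `loss_spec` list with `P`, `N`, `beta_P`, `beta_N`, `weighted`.
#' @export
loss_spec <- function(P, N) {
  if (P < 0 || N < 0) abort_ramil("counts must be nonnegative.")
  if (P == 0 || N == 0) {
    warning("single-class training counts; falling back to unweighted cross entropy.",
            call. = FALSE)
    return(structure(list(P = P, N = N, beta_P = 1, beta_N = 1,
                          weighted = FALSE), class = "loss_spec"))
  }
  structure(list(P = P, N = N, beta_P = N / (P + N), beta_N = P / (P + N),
                 weighted = TRUE), class = "loss_spec")
}

#' Weighted binary cross entropy over a set of bags
#'
#' `L = beta_P * sum_{Y=1} -log q  +  beta_N * sum_{Y=0} -log(1 - q)`,
#' a sum (not a mean) over bags. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` for log stability. With `P = N` the loss equals half
#' the unweighted cross-entropy sum.
#'
#' @param probabilities Predicted bag probabilities.
#' @param labels Binary bag labels.
#' @param spec A [loss_spec()].
#' @param clamp_eps Probability clamp.
#' @return Nonnegative scalar loss.
#' @export
weighted_bce <- function(probabilities, labels, spec, clamp_eps = 1e-7) {
  stopifnot(length(probabilities) == length(labels))
  if (!is_binary(labels)) abort_ramil("labels must be 0/1.")
  q <- clamp(probabilities, clamp_eps, 1 - clamp_eps)
  pos <- labels == 1
  spec$beta_P * sum(-log(q[pos])) + spec$beta_N * sum(-log(1 - q[!pos]))
}
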