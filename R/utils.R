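# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness flows through this
# so that a spec/config seed fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

sigmoid <- function(x) stats::plogis(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a child seed from a master seed; kept < 2^31 so it is a valid R seed
child_seed <- function(seed, stream) {
  (as.double(seed) * 1009 + 97 * stream) %% 2147483647
}

is_binary <- function(x) all(x %in% c(0L, 1L, 0, 1))

abort_ramil <- function(msg, class = "ramil_error") {
  rlang::abort(msg, class = class)
}

`%||%` <- rlang::`%||%`
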