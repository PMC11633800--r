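test_that("attention scores normalize, respect symmetry, and match scalar arithmetic", {
  p <- attention_params(4, D = 8, seed = 1)
  H1 <- matrix(rnorm(4), 1, 4)
  expect_equal(attention_scores(H1, p), 1)                    # softmax of a singleton

  Hsym <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(0, 0, 1, 0))
  a <- attention_scores(Hsym, p)
  expect_equal(sum(a), 1, tolerance = 1e-6)
  expect_equal(a[1], a[2])                                     # identical rows tie

  # direct scalar softmax oracle: L = 2, D = 1, V = [1 0], w = 1
  p2 <- list(V = matrix(c(1, 0), 1, 2), w = 1)
  a2 <- attention_scores(rbind(c(10, 0), c(0, 0)), p2)
  expect_equal(a2, c(exp(tanh(10)) / (exp(tanh(10)) + 1),
                     1 / (exp(tanh(10)) + 1)), tolerance = 1e-6)
  expect_equal(round(a2, 4), c(0.7311, 0.2689))

  expect_error(attention_scores(matrix(0, 2, 3), p), "mismatch")
})

test_that("attention normalization holds across many random bags", {
  p <- attention_params(6, D = 16, seed = 2)
  with_test_seed(3, {
    for (i in 1:50) {
      H <- matrix(rnorm(sample(1:25, 1) * 6, sd = 10), ncol = 6)
      a <- attention_scores(H, p)
      expect_true(all(a >= 0 & a <= 1))
      expect_equal(sum(a), 1, tolerance = 1e-6)
    }
  })
})

test_that("rank_select keeps stable descending order, ties by lower index", {
  H <- diag(3)
  sel <- rank_select(c(0.1, 0.5, 0.4), H, 2)
  expect_equal(sel$indices, c(2, 3))
  expect_equal(sel$scores, c(0.5, 0.4))                 # exact copies, no rescale
  expect_equal(sel$features, H[c(2, 3), ])

  tie <- rank_select(c(0.4, 0.4, 0.2), diag(3), 1)
  expect_equal(tie$indices, 1)                          # lower index wins ties

  clamp <- rank_select(c(0.2, 0.5, 0.3), diag(3), 10)
  expect_equal(clamp$indices, c(2, 3, 1))               # C >= K keeps everything

  expect_error(rank_select(c(0.5, 0.5), diag(2), 0),
               class = "ramil_invalid_config")
})

test_that("rank_select agrees with a brute-force selection oracle under ties", {
  with_test_seed(11, {
    for (i in 1:1000) {
      K <- sample(1:30, 1)
      a <- sample(round(runif(K), 2))                   # 2 d.p. forces ties
      C <- sample(1:K, 1)
      sel <- rank_select(a, matrix(0, K, 1), C)
      expect_identical(sel$indices, oracle_select(a, C))
    }
  })
})

test_that("aggregation is the exact unrescaled weighted sum", {
  sel <- rank_select(c(1), matrix(c(3, -2, 7), 1), 1)
  expect_equal(aggregate_selection(sel), c(3, -2, 7))   # single instance, a = 1

  H <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  sel2 <- rank_select(c(0.5, 0.4, 0.1), H, 2)
  expect_equal(aggregate_selection(sel2), c(0.5, 0.4, 0))

  expect_equal(aggregate_selection(rank_select(c(0.6, 0.4), matrix(0, 2, 4), 2)),
               rep(0, 4))
})

test_that("the sum of selected scores grows with C up to one", {
  p <- attention_params(5, D = 8, seed = 4)
  H <- with_test_seed(5, matrix(rnorm(40), 8, 5))
  a <- attention_scores(H, p)
  sums <- vapply(1:8, function(C) sum(rank_select(a, H, C)$scores), numeric(1))
  expect_true(all(diff(sums) > 0))
  expect_equal(sums[8], 1, tolerance = 1e-6)
})

test_that("the sigmoid head behaves as specified", {
  expect_equal(classify_embedding(c(1, 2), list(weight = c(0, 0), bias = 0)), 0.5)
  expect_equal(classify_embedding(c(0, 0), list(weight = c(1, 1), bias = 50)), 1,
               tolerance = 1e-6)
  b <- seq(-5, 5, by = 1)
  probs <- vapply(b, function(bi) {
    classify_embedding(c(1), list(weight = 0.5, bias = bi))
  }, numeric(1))
  expect_true(all(diff(probs) > 0))                     # monotone in the bias
})

test_that("forward composition equals stepwise application", {
  p <- attention_params(6, D = 12, seed = 6)
  head <- list(weight = with_test_seed(7, rnorm(6)), bias = 0.2)
  H <- with_test_seed(8, matrix(rnorm(60), 10, 6))
  f <- mil_forward(H, p, head, C = 4, "ramil")
  a <- attention_scores(H, p)
  sel <- rank_select(a, H, 4)
  z <- aggregate_selection(sel)
  expect_identical(f$scores, a)
  expect_identical(f$selection$indices, sel$indices)
  expect_identical(f$z, z)
  expect_identical(f$prob, classify_embedding(z, head))
})

test_that("ranking attention with C >= K is bit-identical to attention pooling", {
  p <- attention_params(8, D = 16, seed = 9)
  head <- list(weight = with_test_seed(9, rnorm(8)), bias = -0.1)
  with_test_seed(10, {
    for (i in 1:100) {
      K <- sample(1:15, 1)
      H <- matrix(rnorm(K * 8), K, 8)
      f_ramil <- mil_forward(H, p, head, C = K + sample(0:5, 1), "ramil")
      f_attn <- mil_forward(H, p, head, C = 999, "attention")
      expect_identical(f_ramil$z, f_attn$z)
      expect_identical(f_ramil$prob, f_attn$prob)
    }
  })
})

test_that("permuting slices permutes scores and preserves the probability", {
  p <- attention_params(5, D = 8, seed = 12)
  head <- list(weight = with_test_seed(13, rnorm(5)), bias = 0)
  with_test_seed(14, {
    for (i in 1:20) {
      H <- matrix(rnorm(12 * 5), 12, 5)
      perm <- sample(12)
      f1 <- mil_forward(H, p, head, C = 5, "ramil")
      f2 <- mil_forward(H[perm, ], p, head, C = 5, "ramil")
      expect_equal(f2$scores, f1$scores[perm], tolerance = 1e-12)
      expect_equal(f2$prob, f1$prob, tolerance = 1e-9)
    }
  })
})

test_that("mean and max pooling are columnwise and ordered", {
  H <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(pool_mean(H), c(0.5, 0.5, 0))
  expect_equal(pool_max(H), c(1, 1, 0))
  expect_equal(pool_mean(H[1, , drop = FALSE]), H[1, ])
  expect_equal(pool_max(H[1, , drop = FALSE]), H[1, ])
  Hr <- with_test_seed(15, matrix(rnorm(40), 8, 5))
  expect_true(all(pool_mean(Hr) <= pool_max(Hr)))
})

test_that("gated attention gates the logits and normalizes", {
  p <- attention_params(4, D = 6, gated = TRUE, seed = 16)
  H1 <- matrix(rnorm(4), 1, 4)
  expect_equal(pool_gated_attention(H1, p)$scores, 1)
  Hsym <- rbind(c(1, 0, 2, 1), c(1, 0, 2, 1))
  g <- pool_gated_attention(Hsym, p)
  expect_equal(g$scores, c(0.5, 0.5))
  # U = 0 gates everything at 1/2: scores equal plain attention at half scale
  p0 <- p
  p0$U <- p$U * 0
  H <- with_test_seed(17, matrix(rnorm(24), 6, 4))
  half <- list(V = p$V, w = p$w / 2)
  expect_equal(pool_gated_attention(H, p0)$scores,
               attention_scores(H, half), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences for every variant", {
  with_test_seed(18, {
    H <- matrix(rnorm(3 * 4), 3, 4)
    head <- list(weight = rnorm(4), bias = 0.1)
    for (variant in c("ramil", "attention", "gated", "mean", "max")) {
      p <- attention_params(4, D = 5, gated = variant == "gated", seed = 19)
      loss_of <- function(pp, hh, HH) {
        f <- mil_forward(HH, pp, hh, C = 2, variant)
        -log(1 - f$prob)
      }
      f <- mil_forward(H, p, head, C = 2, variant)
      g <- ramil:::mil_backward(H, p, head, f, dlogit = f$prob, variant)
      eps <- 1e-6
      check <- function(analytic, bump) {
        num <- vapply(seq_along(analytic), function(i) {
          (bump(i, eps) - bump(i, -eps)) / (2 * eps)
        }, numeric(1))
        expect_equal(as.numeric(analytic), num, tolerance = 1e-4)
      }
      if (variant %in% c("ramil", "attention", "gated")) {
        check(g$V, function(i, e) { pp <- p; pp$V[i] <- pp$V[i] + e; loss_of(pp, head, H) })
        check(g$w, function(i, e) { pp <- p; pp$w[i] <- pp$w[i] + e; loss_of(pp, head, H) })
      }
      if (variant == "gated") {
        check(g$U, function(i, e) { pp <- p; pp$U[i] <- pp$U[i] + e; loss_of(pp, head, H) })
      }
      check(g$head_weight, function(i, e) {
        hh <- head; hh$weight[i] <- hh$weight[i] + e; loss_of(p, hh, H)
      })
      check(g$dH, function(i, e) { HH <- H; HH[i] <- HH[i] + e; loss_of(p, head, HH) })
    }
  })
})
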