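test_that("confusion counts apply the >= threshold rule", {
  cc <- confusion_counts(c(0.9, 0.1), c(1, 0))
  expect_equal(unclass(cc)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 0L, FN = 0L, TN = 1L),
               ignore_attr = TRUE)
  on_edge <- confusion_counts(c(0.5), c(1))
  expect_equal(on_edge$TP, 1)                          # exactly 0.5 is positive
  expect_error(confusion_counts(numeric(0), numeric(0)), "empty")
})

test_that("degenerate ratios report zero with a warning and stay consistent", {
  cc <- list(TP = 0, FP = 0, FN = 0, TN = 5)
  w <- capture_warnings(m <- classification_metrics(cc))
  expect_true(any(grepl("0/0", w)))   # precision, recall and F1 all degenerate
  expect_equal(m$acc, 1)
  expect_equal(m$pre, 0)
  expect_equal(m$f1, 0)
  # metric consistency: acc = (rec * n_pos + spe * n_neg) / n on random counts
  with_test_seed(1, {
    for (i in 1:50) {
      cc_i <- list(TP = sample(0:20, 1), FP = sample(0:20, 1),
                   FN = sample(0:20, 1), TN = sample(0:20, 1))
      n_pos <- cc_i$TP + cc_i$FN
      n_neg <- cc_i$FP + cc_i$TN
      if (n_pos == 0 || n_neg == 0) next
      m_i <- suppressWarnings(classification_metrics(cc_i))
      expect_equal(m_i$acc,
                   (m_i$rec * n_pos + m_i$spe * n_neg) / (n_pos + n_neg))
    }
  })
})

test_that("rank AUC matches hand cases and the brute-force pairwise oracle", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_rank(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc_rank(c(0.1, 0.2), c(1, 1)), "both classes")

  with_test_seed(2, {
    for (i in 1:500) {
      n <- sample(4:25, 1)
      labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- sample(round(runif(n), 1))              # coarse grid forces ties
      expect_equal(auc_rank(scores, labels), oracle_auc(scores, labels))
    }
  })
})

test_that("AUC equals U / (n_pos * n_neg) and matches pROC", {
  skip_if_not_installed("pROC")
  with_test_seed(3, {
    for (i in 1:20) {
      n <- 30
      labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- runif(n)
      u <- oracle_u(scores[labels == 1], scores[labels == 0])
      expect_equal(auc_rank(scores, labels),
                   u / (sum(labels == 1) * sum(labels == 0)))
      proc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<")))
      expect_equal(auc_rank(scores, labels), proc, tolerance = 1e-12)
    }
  })
})

test_that("the bootstrap interval is deterministic per seed and covers the point estimate", {
  with_test_seed(4, {
    misses <- 0
    for (i in 1:30) {
      n <- 40
      labels <- sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
      if (length(unique(labels)) < 2) next
      scores <- runif(n) + 0.8 * labels
      a <- auc_rank(scores, labels)
      ci <- auc_ci(scores, labels, n_boot = 400, seed = i)
      if (a < ci["lower"] || a > ci["upper"]) misses <- misses + 1
      expect_identical(ci, auc_ci(scores, labels, n_boot = 400, seed = i))
    }
    expect_lte(misses, 1)
  })
})

test_that("Mann-Whitney U matches pair counting, symmetry and wilcox.test", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)                                # complete separation
  expect_equal(res$U, oracle_u(c(1, 2, 3), c(4, 5, 6)))

  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8)                               # n_a * n_b / 2
  expect_equal(same$p_value, 1)

  with_test_seed(5, {
    for (i in 1:50) {
      a <- round(runif(sample(3:10, 1)), 1)
      b <- round(runif(sample(3:10, 1)), 1)
      res_i <- mann_whitney_u(a, b)
      expect_equal(res_i$U, oracle_u(a, b))
      # U_a + U_b = n_a * n_b
      expect_equal(res_i$U + mann_whitney_u(b, a)$U, length(a) * length(b))
      expect_gte(res_i$p_value, 0)
      expect_lte(res_i$p_value, 1)
    }
    # large-sample normal approximation against wilcox.test (no ties)
    for (i in 1:10) {
      a <- rnorm(25); b <- rnorm(30) + 0.5
      res_i <- mann_whitney_u(a, b)
      ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                 correct = FALSE))
      expect_equal(res_i$U, unname(ref$statistic))
      expect_equal(res_i$p_value, ref$p.value, tolerance = 1e-9)
    }
  })
})

test_that("exact enumeration matches wilcox.test for small tie-free samples", {
  with_test_seed(6, {
    for (i in 1:10) {
      a <- rnorm(5); b <- rnorm(6)
      res <- mann_whitney_u(a, b)
      expect_match(res$method, "exact")
      ref <- stats::wilcox.test(a, b, exact = TRUE)
      expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
    }
  })
})

test_that("ROC points trace a valid staircase", {
  pts <- roc_points(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})
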