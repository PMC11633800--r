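make_labelled_bags <- function(n, n_pos) {
  tibble::tibble(
    patient_id = sprintf("p%03d", seq_len(n)),
    label = c(rep(1L, n_pos), rep(0L, n - n_pos)),
    K = 2L,
    features = replicate(n, matrix(rnorm(4), 2, 2), simplify = FALSE)
  )
}

test_that("validation split is stratified, disjoint and sized by rounding", {
  bags <- with_test_seed(1, make_labelled_bags(241, 95))
  sp <- split_validation(bags, 0.10, seed = 7)
  expect_equal(nrow(sp$val), 24)                        # round(241 * 0.1)
  expect_equal(nrow(sp$train) + nrow(sp$val), 241)
  expect_length(intersect(sp$train$patient_id, sp$val$patient_id), 0)
  # class ratio preserved within one bag
  expect_equal(sum(sp$val$label), 24 * 95 / 241, tolerance = 1)
  expect_gte(sum(sp$val$label), 1)
  expect_gte(sum(sp$val$label == 0), 1)
  # per-seed determinism
  sp2 <- split_validation(bags, 0.10, seed = 7)
  expect_identical(sp$val$patient_id, sp2$val$patient_id)
  expect_false(identical(sp$val$patient_id,
                         split_validation(bags, 0.10, seed = 8)$val$patient_id))
})

test_that("stratified k-fold balances positives and partitions exactly", {
  bags <- with_test_seed(2, make_labelled_bags(241, 95))
  folds <- stratified_kfold(bags, k = 5, seed = 3)
  expect_length(folds, 5)
  expect_equal(sort(unlist(folds)), 1:241)              # disjoint and exhaustive
  pos_counts <- vapply(folds, function(f) sum(bags$label[f]), numeric(1))
  expect_equal(pos_counts, rep(19, 5))                  # 95 / 5 exactly
  expect_identical(stratified_kfold(bags, 5, seed = 3), folds)
})

test_that("augmentation transforms behave and reproduce under a seed", {
  x <- with_test_seed(4, matrix(runif(64 * 64), 64, 64))
  none <- augment_spec(hflip_p = 0, vflip_p = 0, rotate_p = 0)
  expect_identical(augment_slice(x, none), x)

  always_h <- augment_spec(hflip_p = 1, vflip_p = 0, rotate_p = 0)
  once <- augment_slice(x, always_h)
  expect_identical(once, x[, 64:1])
  expect_identical(augment_slice(once, always_h), x)    # involution

  rot <- augment_spec(hflip_p = 0, vflip_p = 0, rotate_p = 1,
                      rotate_range = c(20, 20))
  r1 <- augment_slice(x, rot)
  expect_equal(dim(r1), dim(x))
  expect_false(identical(r1, x))

  full <- augment_spec()
  a1 <- with_test_seed(5, augment_slice(x, full))
  a2 <- with_test_seed(5, augment_slice(x, full))
  expect_identical(a1, a2)
})

test_that("early-stopping bookkeeping restores the strict argmax epoch", {
  trace <- c(0.6, 0.7, 0.7, 0.65, 0.72, 0.72, 0.70)
  st <- NULL
  for (e in seq_along(trace)) st <- ramil:::update_early_stop(st, trace[e], e)
  expect_equal(st$best_epoch, 5)                        # first strict maximum
  expect_equal(st$best, 0.72)
  expect_equal(st$stale, 2)                             # epochs 6, 7 no strict gain

  flat <- rep(0.5, 6)
  st2 <- NULL
  for (e in seq_along(flat)) st2 <- ramil:::update_early_stop(st2, flat[e], e)
  expect_equal(st2$best_epoch, 1)
  expect_equal(st2$stale, 5)                            # stops at patience + 1 epochs
})

test_that("training requires both classes and records a coherent history", {
  single <- make_labelled_bags(10, 10)
  expect_error(suppressWarnings(train_mil(single, fast_config())),
               class = "ramil_single_class")

  m <- tiny_model()
  h <- m$history
  expect_true(all(c("epoch", "train_loss", "val_auc") %in% names(h)))
  expect_equal(h$epoch, seq_len(nrow(h)))
  expect_equal(m$best_val_auc, max(h$val_auc))
  expect_equal(h$val_auc[m$best_epoch], m$best_val_auc)
  expect_lte(nrow(h), fast_config()$max_epochs)
  # loss decreases from start to best region
  expect_lt(min(h$train_loss), h$train_loss[1])
})

test_that("training with the same seed is fully reproducible", {
  bags <- tiny_bags(seed = 31, n_bags = 30)
  m1 <- train_mil(bags, fast_config(seed = 5))
  m2 <- train_mil(bags, fast_config(seed = 5))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  m3 <- train_mil(bags, fast_config(seed = 6))
  expect_false(identical(m1$params$V, m3$params$V))
})

test_that("a learnable signal is actually learned at small scale", {
  train <- tiny_bags(seed = 41, n_bags = 120)
  test <- tiny_bags(seed = 42, n_bags = 40)
  m <- train_mil(train, synthetic_train_config(seed = 2, max_epochs = 60),
                 encoder = feature_projection_encoder(8, seed = 2))
  pr <- predict(m, test)
  expect_gt(auc_rank(pr$prob, pr$label), 0.75)
  # attention prefers witness instances on average
  pos <- which(test$label == 1)
  sep <- vapply(pos, function(i) {
    H <- test$features[[i]] %*% t(m$encoder$params$W)
    a <- attention_scores(H, m$params)
    w <- test$witness[[i]] == 1
    mean(a[w]) - mean(a[!w])
  }, numeric(1))
  expect_gt(mean(sep > 0), 0.5)
})

test_that("variant baselines train end to end on the same data", {
  bags <- tiny_bags(seed = 51, n_bags = 40)
  for (v in c("gated", "mean", "max")) {
    m <- train_mil(bags, fast_config(max_epochs = 5, patience = 4), variant = v)
    expect_s3_class(m, "ramil_model")
    pr <- predict(m, bags)
    expect_true(all(pr$prob > 0 & pr$prob < 1))
  }
})

test_that("tidy and glance summarize a fitted model", {
  m <- tiny_model()
  td <- tidy(m)
  expect_true(all(c("V", "w", "head_weight", "head_bias") %in% td$term))
  expect_true(all(td$l2_norm >= 0))
  gl <- glance(m)
  expect_equal(gl$variant, "ramil")
  expect_equal(gl$best_epoch, m$best_epoch)
  expect_equal(gl$beta_P + gl$beta_N, 1)
})
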