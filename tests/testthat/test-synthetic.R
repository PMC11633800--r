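test_that("feature-bag generator honors counts, shapes and label consistency", {
  spec <- synthetic_spec(n_bags = 100, positive_fraction = 0.4, K = 12,
                         m_witnesses = 3, effect_size = 1.5, noise_sd = 1,
                         mode = "feature_space", L = 6, seed = 42)
  bags <- generate_feature_bags(spec)
  expect_equal(nrow(bags), 100)
  expect_equal(sum(bags$label), 40)                   # exact realized fraction
  expect_true(all(vapply(bags$features, function(H) all(dim(H) == c(12, 6)),
                         logical(1))))
  # label = max(witness flags), and positive bags carry exactly m witnesses
  expect_equal(bags$label, vapply(bags$witness, max, integer(1)))
  expect_true(all(vapply(bags$witness, sum, integer(1))[bags$label == 1] == 3))
  expect_true(all(vapply(bags$witness, sum, integer(1))[bags$label == 0] == 0))
})

test_that("zero positive fraction yields all-negative bags with no witnesses", {
  bags <- generate_feature_bags(
    synthetic_spec(n_bags = 20, positive_fraction = 0, m_witnesses = 0,
                   mode = "feature_space", seed = 1))
  expect_true(all(bags$label == 0))
  expect_true(all(unlist(bags$witness) == 0))
})

test_that("generation is bit-identical under a fixed seed and leaves the RNG alone", {
  spec <- tiny_feature_spec(seed = 7)
  set.seed(123)
  before <- .Random.seed
  b1 <- generate_feature_bags(spec)
  expect_identical(.Random.seed, before)
  b2 <- generate_feature_bags(spec)
  expect_identical(b1, b2)
  b3 <- generate_feature_bags(tiny_feature_spec(seed = 8))
  expect_false(identical(b1$features[[1]], b3$features[[1]]))
})

test_that("witness shift moves instances by effect_size along the signal direction", {
  spec <- synthetic_spec(n_bags = 200, positive_fraction = 0.5, K = 10,
                         m_witnesses = 2, effect_size = 3, noise_sd = 1,
                         mode = "feature_space", L = 16, seed = 9)
  bags <- generate_feature_bags(spec)
  H <- do.call(rbind, bags$features)
  w <- unlist(bags$witness)
  proj <- H %*% rep(1 / 4, 16)             # unit direction for L = 16
  expect_equal(mean(proj[w == 1]) - mean(proj[w == 0]), 3, tolerance = 0.15)
  # orthogonal directions carry no shift
  orth <- H %*% c(1, -1, rep(0, 14)) / sqrt(2)
  expect_lt(abs(mean(orth[w == 1]) - mean(orth[w == 0])), 0.3)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(m_witnesses = 30, K = 20), class = "ramil_invalid_spec")
  expect_error(synthetic_spec(n_bags = 1), class = "ramil_invalid_spec")
  expect_error(synthetic_spec(noise_sd = 0), class = "ramil_invalid_spec")
  expect_error(
    generate_feature_bags(synthetic_spec(mode = "image")),
    class = "ramil_invalid_spec")
  expect_error(
    generate_image_bags(synthetic_spec(mode = "feature_space")),
    class = "ramil_invalid_spec")
})

test_that("image bags mark blob slices and witness slices are brighter on average", {
  spec <- synthetic_spec(n_bags = 50, positive_fraction = 0.6, K = 20,
                         m_witnesses = 3, effect_size = 2, noise_sd = 0.1,
                         mode = "image", L = 4, seed = 13, image_size = 96)
  bags <- generate_image_bags(spec, blob_sigma = 6)
  expect_true(all(vapply(bags$witness, sum, integer(1))[bags$label == 1] == 3))
  expect_true(all(vapply(bags$slices, function(v) all(v >= 0 & v <= 1),
                         logical(1))))
  means <- unlist(lapply(bags$slices, function(v) apply(v, 3, mean)))
  w <- unlist(bags$witness)
  expect_gt(mean(means[w == 1]), mean(means[w == 0]))
  # blob metadata points at witness slices only
  for (i in which(bags$label == 1)) {
    expect_setequal(bags$blobs[[i]]$slice, which(bags$witness[[i]] == 1))
  }
})

test_that("zero effect size makes witness and background slices indistinguishable", {
  spec <- synthetic_spec(n_bags = 50, positive_fraction = 0.6, K = 10,
                         m_witnesses = 2, effect_size = 0, noise_sd = 0.1,
                         mode = "image", L = 4, seed = 21, image_size = 64)
  bags <- generate_image_bags(spec, blob_sigma = 6)
  means <- unlist(lapply(bags$slices, function(v) apply(v, 3, mean)))
  w <- unlist(bags$witness)
  ks <- suppressWarnings(stats::ks.test(means[w == 1], means[w == 0]))
  expect_gt(ks$p.value, 0.01)
})

test_that("centered placement concentrates witnesses in middle slices", {
  spec_c <- synthetic_spec(n_bags = 200, positive_fraction = 1 - 1e-9, K = 21,
                           m_witnesses = 1, mode = "feature_space", L = 4,
                           seed = 5, placement = "centered")
  spec_u <- synthetic_spec(n_bags = 200, positive_fraction = 1 - 1e-9, K = 21,
                           m_witnesses = 1, mode = "feature_space", L = 4,
                           seed = 5, placement = "uniform")
  pos_of <- function(bags) {
    unlist(lapply(bags$witness[bags$label == 1], function(w) which(w == 1)))
  }
  d_c <- mean(abs(pos_of(generate_feature_bags(spec_c)) - 11))
  d_u <- mean(abs(pos_of(generate_feature_bags(spec_u)) - 11))
  expect_lt(d_c, d_u)
})
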