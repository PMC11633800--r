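# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

tiny_feature_spec <- function(seed = 3, n_bags = 60, L = 8, K = 10) {
  synthetic_spec(n_bags = n_bags, positive_fraction = 0.4, K = K,
                 m_witnesses = 2, effect_size = 2, noise_sd = 1,
                 mode = "feature_space", L = L, seed = seed)
}

tiny_bags <- function(...) generate_feature_bags(tiny_feature_spec(...))

fast_config <- function(seed = 1, ...) {
  synthetic_train_config(seed = seed, max_epochs = 15, patience = 10, ...)
}

# small trained model on tiny feature bags, shared across test files
tiny_model <- function() {
  cache_fixture("tiny_model", function() {
    train_mil(tiny_bags(), fast_config())
  })
}

# image fixture: frozen conv encoder + standardized features + trained model;
# slices kept so Grad-CAM can attribute through the encoder
image_fixture <- function() {
  cache_fixture("image_fixture", function() {
    spec <- synthetic_spec(n_bags = 60, positive_fraction = 0.5, K = 20,
                           m_witnesses = 3, effect_size = 2, noise_sd = 0.1,
                           mode = "image", L = 16, seed = 11)
    bags <- generate_image_bags(spec)
    enc <- build_encoder(encoder_spec("conv", output_dim = 16,
                                      trainable = FALSE, seed = 2))
    bags <- encode_bags(bags, enc)
    train_idx <- 1:40
    bags <- standardize_features(bags, bags[train_idx, ])
    stats <- list(mean = attr(bags, "feature_mean"),
                  sd = attr(bags, "feature_sd"))
    model <- train_mil(bags[train_idx, ],
                       synthetic_train_config(seed = 1, max_epochs = 60))
    list(spec = spec, encoder = enc, stats = stats, model = model,
         train = bags[train_idx, ], test = bags[-train_idx, ])
  })
}

# brute-force selection oracle: repeated scan for the maximum score with the
# lowest index among the remaining candidates
oracle_select <- function(a, C) {
  remaining <- seq_along(a)
  out <- integer(0)
  for (i in seq_len(min(C, length(a)))) {
    best <- remaining[which.max(a[remaining])]  # which.max takes first on ties
    out <- c(out, best)
    remaining <- setdiff(remaining, best)
  }
  out
}

# brute-force AUC: count positive-over-negative wins, half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# brute-force U statistic by pair counting
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# one synthetic DICOM series in a temp dir; returns dir and the pixel truth
make_dicom_series <- function(n = 4, size = 16, shuffle_names = FALSE,
                              seed = 5) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  slices <- with_test_seed(seed, lapply(seq_len(n), function(i) {
    matrix(runif(size * size), size, size)
  }))
  order_names <- if (shuffle_names) rev(seq_len(n)) else seq_len(n)
  for (i in seq_len(n)) {
    write_dicom_slice(slices[[i]],
                      file.path(dir, sprintf("img_%02d.dcm", order_names[i])),
                      instance_number = i,
                      position = c(0, 0, 2.5 * i))
  }
  list(dir = dir, slices = slices)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
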