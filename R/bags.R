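#' Describe a synthetic witness-bag dataset
#'
#' A bag is one subject's ordered sequence of `K` instances (2D slices of a
#' volume, or their feature vectors) carrying a single binary label. In the
#' weak-supervision setting modelled here, a positive bag contains `m_witnesses`
#' "witness" instances that carry the discriminative signal while every other
#' instance is background; instance labels exist but are never shown to the
#' learner. The spec object fixes the generating conditions.
#'
#' @param n_bags Number of bags to generate (at least 2).
#' @param positive_fraction Fraction of positive bags in `[0, 1)`. The realized
#'   positive count is `round(n_bags * positive_fraction)`, exactly.
#' @param K Instances per bag.
#' @param m_witnesses Witness instances per positive bag (`<= K`).
#' @param effect_size Mean shift of the witness signal, in units of the
#'   background standard deviation (feature mode) or as a multiplier of the
#'   blob amplitude (image mode). `0` makes positives and negatives
#'   distributionally identical.
#' @param noise_sd Standard deviation of the background noise.
#' @param mode `"feature_space"` (bags of `K x L` feature matrices) or
#'   `"image"` (bags of `K` grayscale slices).
#' @param L Feature dimension (feature-space mode only).
#' @param seed Integer seed; a fixed seed reproduces the dataset bit for bit.
#' @param placement `"uniform"` places witnesses uniformly at random without
#'   replacement among the `K` indices; `"centered"` concentrates them in the
#'   middle indices, emulating volumes whose informative slices cluster
#'   centrally.
#' @param image_size Side length of generated square slices (image mode).
#'
#' @return An object of class `ramil_spec`.
#' @export
synthetic_spec <- function(n_bags = 100L,
                           positive_fraction = 0.4,
                           K = 20L,
                           m_witnesses = 3L,
                           effect_size = 2,
                           noise_sd = 1,
                           mode = c("feature_space", "image"),
                           L = 32L,
                           seed = 1L,
                           placement = c("uniform", "centered"),
                           image_size = 224L) {
  mode <- match.arg(mode)
  placement <- match.arg(placement)
  if (n_bags < 2) abort_ramil("`n_bags` must be at least 2.", "ramil_invalid_spec")
  if (positive_fraction < 0 || positive_fraction >= 1) {
    abort_ramil("`positive_fraction` must lie in [0, 1).", "ramil_invalid_spec")
  }
  if (K < 1) abort_ramil("`K` must be a positive integer.", "ramil_invalid_spec")
  if (m_witnesses > K) {
    abort_ramil("`m_witnesses` cannot exceed `K`.", "ramil_invalid_spec")
  }
  if (positive_fraction > 0 && m_witnesses < 1) {
    abort_ramil("positive bags require `m_witnesses` >= 1.", "ramil_invalid_spec")
  }
  if (noise_sd <= 0) abort_ramil("`noise_sd` must be positive.", "ramil_invalid_spec")
  if (effect_size < 0) abort_ramil("`effect_size` must be nonnegative.", "ramil_invalid_spec")
  structure(
    list(
      n_bags = as.integer(n_bags), positive_fraction = positive_fraction,
      K = as.integer(K), m_witnesses = as.integer(m_witnesses),
      effect_size = effect_size, noise_sd = noise_sd, mode = mode,
      L = as.integer(L), seed = as.integer(seed), placement = placement,
      image_size = as.integer(image_size),
      spec_id = paste0("synth-", mode, "-", seed)
    ),
    class = "ramil_spec"
  )
}

#' @export
print.ramil_spec <- function(x, ...) {
  cat("<ramil_spec>", x$spec_id, "\n")
  cat(sprintf("  %d bags (%.0f%% positive), K = %d, m = %d, effect = %g, noise sd = %g\n",
              x$n_bags, 100 * x$positive_fraction, x$K, x$m_witnesses,
              x$effect_size, x$noise_sd))
  if (x$mode == "feature_space") cat(sprintf("  feature mode, L = %d\n", x$L))
  else cat(sprintf("  image mode, %dx%d slices\n", x$image_size, x$image_size))
  invisible(x)
}

# labels honouring the realized positive count exactly, in random order
draw_labels <- function(n_bags, positive_fraction) {
  n_pos <- round(n_bags * positive_fraction)
  sample(c(rep(1L, n_pos), rep(0L, n_bags - n_pos)))
}

witness_positions <- function(K, m, placement) {
  if (m == 0L) return(integer(0))
  if (placement == "centered") {
    # weight middle indices: triangular weights peaking at the volume centre
    w <- 1 + pmin(seq_len(K) - 1, K - seq_len(K))
    sort(sample.int(K, m, prob = w))
  } else {
    sort(sample.int(K, m))
  }
}

#' Generate synthetic feature-space bags
#'
#' Background instances are drawn i.i.d. from a spherical Gaussian with
#' standard deviation `noise_sd`; in positive bags, exactly `m_witnesses`
#' instances have their mean shifted by `effect_size` along a fixed unit
#' signal direction (uniform across all features). Instance-level witness
#' flags are retained as generator ground truth for evaluating attention
#' quality; they are never used in training.
#'
#' @param spec A [synthetic_spec()] with `mode = "feature_space"`.
#' @return A tibble with one row per bag: `patient_id`, `label`, `K`,
#'   `features` (list of `K x L` matrices) and `witness` (list of 0/1
#'   vectors of length `K`).
#' @export
generate_feature_bags <- function(spec) {
  stopifnot(inherits(spec, "ramil_spec"))
  if (spec$mode != "feature_space") {
    abort_ramil("`spec$mode` must be \"feature_space\".", "ramil_invalid_spec")
  }
  L <- spec$L
  direction <- rep(1 / sqrt(L), L)  # fixed unit signal direction
  with_seed(spec$seed, {
    labels <- draw_labels(spec$n_bags, spec$positive_fraction)
    rows <- lapply(seq_len(spec$n_bags), function(b) {
      H <- matrix(stats::rnorm(spec$K * L, sd = spec$noise_sd), spec$K, L)
      flags <- integer(spec$K)
      if (labels[b] == 1L) {
        pos <- witness_positions(spec$K, spec$m_witnesses, spec$placement)
        flags[pos] <- 1L
        H[pos, ] <- H[pos, , drop = FALSE] +
          matrix(spec$effect_size * direction, length(pos), L, byrow = TRUE)
      }
      list(features = H, witness = flags)
    })
    tibble::tibble(
      patient_id = sprintf("synth-%04d", seq_len(spec$n_bags)),
      label = labels,
      K = spec$K,
      features = lapply(rows, `[[`, "features"),
      witness = lapply(rows, `[[`, "witness")
    )
  })
}

# one noisy background slice, values clipped to [0, 1]
background_slice <- function(size, noise_sd) {
  clamp(matrix(stats::rnorm(size * size, mean = 0.25, sd = noise_sd), size, size), 0, 1)
}

gaussian_blob <- function(size, row0, col0, sigma, amplitude) {
  r <- matrix(seq_len(size), size, size)
  c <- t(r)
  amplitude * exp(-((r - row0)^2 + (c - col0)^2) / (2 * sigma^2))
}

#' Generate synthetic image bags
#'
#' Every slice is clipped Gaussian background noise; witness slices
#' additionally carry a bright Gaussian blob at a random location whose peak
#' amplitude is `0.25 * effect_size`. Blob centres and widths are recorded per
#' bag as generator ground truth for localization checks.
#'
#' @param spec A [synthetic_spec()] with `mode = "image"`.
#' @param blob_sigma Blob standard deviation in pixels.
#' @return A tibble with one row per bag: `patient_id`, `label`, `K`,
#'   `slices` (list of `size x size x K` arrays), `witness` (0/1 vectors) and
#'   `blobs` (list of tibbles `slice`, `row`, `col`, `sigma` for witness
#'   slices).
#' @export
generate_image_bags <- function(spec, blob_sigma = 12) {
  stopifnot(inherits(spec, "ramil_spec"))
  if (spec$mode != "image") {
    abort_ramil("`spec$mode` must be \"image\".", "ramil_invalid_spec")
  }
  size <- spec$image_size
  margin <- ceiling(3 * blob_sigma)
  if (2 * margin >= size) abort_ramil("blob does not fit in the slice.", "ramil_invalid_spec")
  amplitude <- 0.25 * spec$effect_size
  with_seed(spec$seed, {
    labels <- draw_labels(spec$n_bags, spec$positive_fraction)
    rows <- lapply(seq_len(spec$n_bags), function(b) {
      vol <- array(0, dim = c(size, size, spec$K))
      flags <- integer(spec$K)
      blobs <- NULL
      pos <- if (labels[b] == 1L) {
        witness_positions(spec$K, spec$m_witnesses, spec$placement)
      } else integer(0)
      flags[pos] <- 1L
      if (length(pos)) {
        blobs <- tibble::tibble(
          slice = pos,
          row = stats::runif(length(pos), margin, size - margin),
          col = stats::runif(length(pos), margin, size - margin),
          sigma = blob_sigma
        )
      }
      for (k in seq_len(spec$K)) {
        sl <- background_slice(size, spec$noise_sd)
        if (flags[k] == 1L) {
          i <- which(blobs$slice == k)
          sl <- clamp(sl + gaussian_blob(size, blobs$row[i], blobs$col[i],
                                         blob_sigma, amplitude), 0, 1)
        }
        vol[, , k] <- sl
      }
      list(slices = vol, witness = flags, blobs = blobs)
    })
    tibble::tibble(
      patient_id = sprintf("synth-%04d", seq_len(spec$n_bags)),
      label = labels,
      K = spec$K,
      slices = lapply(rows, `[[`, "slices"),
      witness = lapply(rows, `[[`, "witness"),
      blobs = lapply(rows, `[[`, "blobs")
    )
  })
}

#' Read a patient manifest
#'
#' The manifest is a CSV with columns `patient_id`, `label` and `slice_dir`
#' (a directory of slice PNGs in acquisition order). Labels are patient-level
#' only, mirroring the weak supervision of the bag model.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with columns `patient_id`, `label`, `slice_dir`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_ramil(paste0("manifest not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    label = readr::col_double(),
    slice_dir = readr::col_character()
  ))
  if (nrow(df) == 0) {
    warning("manifest is empty: ", path, call. = FALSE)
    return(df)
  }
  if (!is_binary(df$label)) {
    abort_ramil("manifest labels must be 0 or 1.", "ramil_invalid_manifest")
  }
  if (anyDuplicated(df$patient_id)) {
    abort_ramil("duplicate patient_id in manifest.", "ramil_invalid_manifest")
  }
  df$label <- as.integer(df$label)
  df
}

#' Write a patient manifest
#'
#' @param records A data frame with `patient_id`, `label` and `slice_dir`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  stopifnot(all(c("patient_id", "label", "slice_dir") %in% names(records)))
  if (!is_binary(records$label)) {
    abort_ramil("manifest labels must be 0 or 1.", "ramil_invalid_manifest")
  }
  if (anyDuplicated(records$patient_id)) {
    abort_ramil("duplicate patient_id in manifest.", "ramil_invalid_manifest")
  }
  readr::write_csv(records[, c("patient_id", "label", "slice_dir")], path)
  invisible(path)
}

#' Write feature-space bags to a plain-text archive
#'
#' One index CSV plus one tab-separated feature matrix (and witness vector,
#' when present) per bag, so archives stay portable and diffable.
#'
#' @param bags A bag tibble from [generate_feature_bags()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_feature_bags <- function(bags, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- tibble::tibble(
    patient_id = bags$patient_id, label = bags$label, K = bags$K,
    L = vapply(bags$features, ncol, integer(1)),
    has_witness = !vapply(bags$witness %||% rep(list(NULL), nrow(bags)),
                          is.null, logical(1))
  )
  readr::write_csv(idx, file.path(dir, "index.csv"))
  for (i in seq_len(nrow(bags))) {
    id <- bags$patient_id[i]
    utils::write.table(bags$features[[i]],
                       file.path(dir, paste0(id, "_features.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    if (idx$has_witness[i]) {
      writeLines(as.character(bags$witness[[i]]),
                 file.path(dir, paste0(id, "_witness.txt")))
    }
  }
  invisible(dir)
}

#' Read feature-space bags written by [write_feature_bags()]
#'
#' @param dir Archive directory.
#' @return A bag tibble.
#' @export
read_feature_bags <- function(dir) {
  idx_path <- file.path(dir, "index.csv")
  if (!file.exists(idx_path)) abort_ramil(paste0("no bag archive at ", dir))
  idx <- readr::read_csv(idx_path, col_types = readr::cols())
  features <- lapply(idx$patient_id, function(id) {
    as.matrix(utils::read.table(file.path(dir, paste0(id, "_features.tsv")),
                                sep = "\t"))
  })
  features <- lapply(features, function(m) {
    dimnames(m) <- NULL
    m
  })
  witness <- lapply(seq_len(nrow(idx)), function(i) {
    if (isTRUE(idx$has_witness[i])) {
      as.integer(readLines(file.path(dir, paste0(idx$patient_id[i], "_witness.txt"))))
    } else NULL
  })
  tibble::tibble(
    patient_id = idx$patient_id, label = as.integer(idx$label),
    K = as.integer(idx$K), features = features, witness = witness
  )
}
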