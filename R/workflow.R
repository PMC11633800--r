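# Experiment plumbing: serializable configs, checkpoints with JSON sidecars,
# and the cmd_* functions behind the command-line interface. Every artifact
# written to disk carries the config hash, seed and package version so runs
# are traceable and reproducible.

config_hash <- function(x) rlang::hash(x)

run_stamp <- function(config, seed) {
  list(config_hash = config_hash(config), seed = seed,
       package_version = as.character(utils::packageVersion("ramil")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_run_manifest <- function(out_dir, stamp, inputs = list()) {
  jsonlite::write_json(c(stamp, list(inputs = inputs)),
                       file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Read an experiment configuration from YAML
#'
#' Recognized top-level keys: `train` ([train_config()] fields), `encoder`
#' ([encoder_spec()] fields), `synthetic` ([synthetic_spec()] fields),
#' `pooling`, `seed`. Missing keys fall back to defaults.
#'
#' @param path YAML file.
#' @return A named list with `train`, `encoder`, `synthetic`, `pooling`,
#'   `seed`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  tr <- raw$train %||% list()
  tr$seed <- tr$seed %||% seed
  aug <- tr$augment
  tr$augment <- if (is.null(aug)) augment_spec() else do.call(augment_spec, aug)
  list(
    train = do.call(train_config, tr),
    encoder = if (!is.null(raw$encoder)) do.call(encoder_spec, raw$encoder) else NULL,
    synthetic = if (!is.null(raw$synthetic)) {
      sy <- raw$synthetic
      sy$seed <- sy$seed %||% seed
      do.call(synthetic_spec, sy)
    } else NULL,
    pooling = raw$pooling %||% "ramil",
    seed = seed
  )
}

#' Save a model checkpoint
#'
#' Weights go to `<path>` (RDS) and a JSON sidecar `<path>.json` records the
#' architecture metadata (L, D, C, variant, encoder name, config hash) used
#' to validate the checkpoint at load time.
#'
#' @param model A `ramil_model`.
#' @param path Checkpoint path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(L = model$L, D = model$config$D, C = model$config$C,
               variant = model$variant,
               encoder = model$encoder$spec$name %||% "identity",
               config_hash = config_hash(model$config),
               package_version = as.character(utils::packageVersion("ramil")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' When `expect` (a list with any of `L`, `D`, `C`) is given, the checkpoint
#' is refused on mismatch unless `force = TRUE`.
#'
#' @param path Checkpoint path from [save_model()].
#' @param expect Optional expected architecture values.
#' @param force Load despite mismatches.
#' @return A `ramil_model`.
#' @export
load_model <- function(path, expect = NULL, force = FALSE) {
  if (!file.exists(path)) abort_ramil(paste0("checkpoint not found: ", path))
  model <- readRDS(path)
  if (!is.null(expect) && !force) {
    have <- list(L = model$L, D = model$config$D, C = model$config$C)
    for (nm in intersect(names(expect), names(have))) {
      if (!identical(as.integer(expect[[nm]]), as.integer(have[[nm]]))) {
        abort_ramil(sprintf(
          "checkpoint %s has %s = %d but config expects %d (use force = TRUE to override).",
          path, nm, have[[nm]], as.integer(expect[[nm]])),
          "ramil_checkpoint_mismatch")
      }
    }
  }
  model
}

#' Generate a synthetic dataset on disk
#'
#' Feature-space bags become a plain-text archive ([write_feature_bags()]);
#' image bags become per-patient PNG directories plus a manifest CSV.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
cmd_simulate <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (spec$mode == "feature_space") {
    bags <- generate_feature_bags(spec)
    write_feature_bags(bags, file.path(out_dir, "bags"))
  } else {
    bags <- generate_image_bags(spec)
    recs <- tibble::tibble(patient_id = bags$patient_id, label = bags$label,
                           slice_dir = file.path("slices", bags$patient_id))
    for (i in seq_len(nrow(bags))) {
      slices_to_png(slice_list(bags$slices[[i]]),
                    file.path(out_dir, recs$slice_dir[i]))
    }
    write_manifest(recs, file.path(out_dir, "manifest.csv"))
    writeLines(jsonlite::toJSON(lapply(bags$witness, identity)),
               file.path(out_dir, "witness.json"))
  }
  write_run_manifest(out_dir, run_stamp(unclass(spec), spec$seed))
  invisible(out_dir)
}

#' Load bags from a dataset directory
#'
#' Accepts either a feature-bag archive ([write_feature_bags()], possibly
#' nested under `bags/`) or an image dataset with a `manifest.csv`.
#'
#' @param data_dir Dataset directory.
#' @return A bag tibble.
#' @export
load_any_bags <- function(data_dir) {
  if (file.exists(file.path(data_dir, "index.csv"))) {
    read_feature_bags(data_dir)
  } else if (file.exists(file.path(data_dir, "bags", "index.csv"))) {
    read_feature_bags(file.path(data_dir, "bags"))
  } else if (file.exists(file.path(data_dir, "manifest.csv"))) {
    load_manifest_bags(file.path(data_dir, "manifest.csv"))
  } else {
    abort_ramil(paste0("no bag archive or manifest under ", data_dir))
  }
}

#' Train a model from a dataset directory
#'
#' @param data_dir Dataset from [cmd_simulate()] (or a manifest directory).
#' @param out_dir Output directory for the checkpoint, history CSV and run
#'   manifest.
#' @param config A [train_config()].
#' @param pooling Pooling variant.
#' @param encoder Optional [encoder_spec()] (required for image bags).
#' @return The fitted `ramil_model`, invisibly.
#' @export
cmd_train <- function(data_dir, out_dir, config = train_config(),
                      pooling = "ramil", encoder = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bags <- load_any_bags(data_dir)
  enc <- if (!is.null(encoder)) build_encoder(encoder)
  model <- train_mil(bags, config, pooling, enc)
  save_model(model, file.path(out_dir, "checkpoint.rds"))
  readr::write_csv(model$history, file.path(out_dir, "history.csv"))
  write_run_manifest(out_dir, run_stamp(config, config$seed),
                     inputs = list(data_dir = data_dir, pooling = pooling))
  invisible(model)
}

#' Evaluate a checkpoint on a dataset
#'
#' @param checkpoint Path from [save_model()].
#' @param data_dir Dataset directory.
#' @param out_path Output JSON report.
#' @param expect,force Architecture validation (see [load_model()]).
#' @param seed Bootstrap seed.
#' @return The `ramil_eval`, invisibly.
#' @export
cmd_evaluate <- function(checkpoint, data_dir, out_path, expect = NULL,
                         force = FALSE, seed = 1L) {
  model <- load_model(checkpoint, expect, force)
  bags <- load_any_bags(data_dir)
  ev <- evaluate_model(model, bags, seed = seed)
  report <- c(as.list(glance(ev)),
              list(threshold = ev$threshold,
                   probabilities = ev$probs,
                   config_hash = config_hash(model$config)))
  dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, out_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(ev)
}

#' Explain one patient from a checkpoint
#'
#' @param checkpoint Model checkpoint path.
#' @param data_dir Dataset directory (image bags).
#' @param patient_id Which bag to explain.
#' @param out_dir Output directory for overlays and the attribution CSV.
#' @return The attribution tibble, invisibly.
#' @export
cmd_explain <- function(checkpoint, data_dir, patient_id, out_dir) {
  model <- load_model(checkpoint)
  bags <- load_any_bags(data_dir)
  bag <- bags[bags$patient_id == patient_id, ]
  if (nrow(bag) != 1) abort_ramil(paste0("patient not found: ", patient_id))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  heatmaps <- !is.null(model$encoder) && model$encoder$spec$name == "conv" &&
    !is.null(bag$slices)
  attribution <- explain_bag(model, bag, heatmaps = heatmaps)
  readr::write_csv(
    attribution[, c("slice", "score", "rank", "selected")],
    file.path(out_dir, "attribution.csv"))
  if (heatmaps) export_overlays(bag, attribution, out_dir)
  invisible(attribution)
}

#' Stratified k-fold cross-validation
#'
#' Trains one model per fold on the remaining folds and evaluates it on the
#' held-out fold; writes one report per fold plus a pooled summary.
#'
#' @param bags Bag tibble.
#' @param config A [train_config()].
#' @param k Number of folds.
#' @param pooling Pooling variant.
#' @param encoder Optional `ramil_encoder`.
#' @param out_dir Optional directory for per-fold JSON reports.
#' @return A `ramil_crossval` list: `folds` (tibble, one row per fold) and
#'   `summary` (means across folds).
#' @export
cmd_crossval <- function(bags, config = train_config(), k = 5L,
                         pooling = "ramil", encoder = NULL, out_dir = NULL) {
  folds <- stratified_kfold(bags, k, child_seed(config$seed, 11))
  rows <- lapply(seq_along(folds), function(i) {
    test <- bags[folds[[i]], ]
    train <- bags[-folds[[i]], ]
    model <- train_mil(train, config, pooling, encoder)
    ev <- evaluate_model(model, test, seed = config$seed)
    row <- dplyr::bind_cols(tibble::tibble(fold = i), eval_row(ev))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(as.list(row), file.path(out_dir, sprintf("fold%d.json", i)),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    row
  })
  fold_tbl <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(fold_tbl,
                              dplyr::across(c("acc", "pre", "rec", "spe", "f1", "auc"),
                                            mean))
  if (!is.null(out_dir)) {
    jsonlite::write_json(as.list(summary), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_run_manifest(out_dir, run_stamp(config, config$seed),
                       inputs = list(k = k, pooling = pooling))
  }
  structure(list(folds = fold_tbl, summary = summary), class = "ramil_crossval")
}

#' @export
print.ramil_crossval <- function(x, ...) {
  cat("<ramil_crossval>", nrow(x$folds), "folds\n")
  print(x$folds)
  cat("pooled means:\n")
  print(x$summary)
  invisible(x)
}
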