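#' Center-crop a slice to a square patch
#'
#' Crops a `size x size` patch from the centre of the slice, keeping the
#' pelvic field of view and discarding boundary regions. Odd remainders use
#' the floor convention: the crop starts at `floor((dim - size) / 2)`
#' (0-based). Inputs smaller than `size` are zero-padded symmetrically first,
#' with a warning.
#'
#' @param x A 2D numeric matrix.
#' @param size Output side length (default 224).
#' @return A `size x size` matrix.
#' @export
center_crop <- function(x, size = 224L) {
  stopifnot(is.matrix(x))
  if (nrow(x) < size || ncol(x) < size) {
    warning(sprintf("input %dx%d smaller than crop %d; zero-padding.",
                    nrow(x), ncol(x), size), call. = FALSE)
    padded <- matrix(0, max(nrow(x), size), max(ncol(x), size))
    r0 <- (nrow(padded) - nrow(x)) %/% 2
    c0 <- (ncol(padded) - ncol(x)) %/% 2
    padded[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x))] <- x
    x <- padded
  }
  r0 <- (nrow(x) - size) %/% 2
  c0 <- (ncol(x) - size) %/% 2
  x[r0 + seq_len(size), c0 + seq_len(size), drop = FALSE]
}

# per-volume min-max scaling to [0, 1]; a constant volume maps to all zeros
minmax_volume <- function(slices) {
  rng <- range(unlist(lapply(slices, range)))
  if (rng[1] == rng[2]) {
    return(lapply(slices, function(s) s * 0))
  }
  lapply(slices, function(s) (s - rng[1]) / (rng[2] - rng[1]))
}

#' Convert a DICOM series directory to an ordered slice sequence
#'
#' Reads every file in `series_dir`, verifies a single coherent series,
#' orders slices by the projection of ImagePositionPatient on the slice
#' normal (falling back to InstanceNumber when geometry tags are absent),
#' and min-max scales intensities to `[0, 1]` per volume. Filename order is
#' never trusted.
#'
#' @param series_dir Directory containing one DICOM series.
#' @param pattern Filename filter passed to [list.files()].
#' @return A list of 2D matrices in `[0, 1]`, in slice-position order.
#' @export
dicom_to_slices <- function(series_dir, pattern = NULL) {
  files <- list.files(series_dir, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) abort_ramil(paste0("no files in series dir: ", series_dir))
  slices <- lapply(files, read_dicom_slice)
  uids <- unique(vapply(slices, `[[`, character(1), "series_uid"))
  uids <- uids[!is.na(uids)]
  if (length(uids) > 1) {
    abort_ramil(paste0("mixed series UIDs in ", series_dir, ": ",
                       paste(uids, collapse = ", ")))
  }
  has_geom <- vapply(slices, function(s) {
    length(s$position) == 3 && length(s$orientation) == 6
  }, logical(1))
  if (all(has_geom)) {
    o <- slices[[1]]$orientation
    normal <- c(o[2] * o[6] - o[3] * o[5],
                o[3] * o[4] - o[1] * o[6],
                o[1] * o[5] - o[2] * o[4])
    key <- vapply(slices, function(s) sum(s$position * normal), numeric(1))
  } else {
    inst <- vapply(slices, `[[`, integer(1), "instance_number")
    if (anyNA(inst)) {
      abort_ramil(paste0(
        "cannot order series in ", series_dir,
        ": position/orientation tags incomplete and instance numbers missing."))
    }
    key <- inst
  }
  ord <- order(key)
  minmax_volume(lapply(slices[ord], function(s) {
    storage.mode(s$pixels) <- "double"
    s$pixels
  }))
}

#' Read a directory of grayscale PNG slices as an ordered sequence
#'
#' Slices are ordered by filename (zero-padded names recommended); values are
#' already in `[0, 1]` as decoded.
#'
#' @param dir Directory of PNG files.
#' @return A list of 2D matrices.
#' @export
png_to_slices <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) abort_ramil(paste0("no PNG slices in ", dir))
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
}

#' Write an ordered slice sequence as PNG files
#'
#' @param slices List of 2D matrices in `[0, 1]`.
#' @param dir Output directory (created if needed).
#' @return Written file paths, invisibly.
#' @export
slices_to_png <- function(slices, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("slice_%03d.png", seq_along(slices)))
  for (i in seq_along(slices)) {
    png::writePNG(clamp(slices[[i]], 0, 1), paths[i])
  }
  invisible(paths)
}

#' Preprocess a volume into a model-ready bag
#'
#' Applies [dicom_to_slices()] or [png_to_slices()], then [center_crop()] to
#' every slice.
#'
#' @param input_dir DICOM series or PNG directory.
#' @param patient_id Identifier for the resulting bag.
#' @param label Optional binary label.
#' @param crop Crop size (default 224).
#' @param format `"dicom"` or `"png"`.
#' @return A one-row bag tibble with a `slices` list-column
#'   (`crop x crop x K` array).
#' @export
preprocess_volume <- function(input_dir, patient_id, label = NA_integer_,
                              crop = 224L, format = c("dicom", "png")) {
  format <- match.arg(format)
  slices <- switch(format,
                   dicom = dicom_to_slices(input_dir),
                   png = png_to_slices(input_dir))
  cropped <- lapply(slices, center_crop, size = crop)
  vol <- array(0, dim = c(crop, crop, length(cropped)))
  for (k in seq_along(cropped)) vol[, , k] <- cropped[[k]]
  tibble::tibble(
    patient_id = patient_id,
    label = as.integer(label),
    K = length(cropped),
    slices = list(vol)
  )
}

#' Load all bags listed in a manifest
#'
#' @param manifest_path Manifest CSV (see [read_manifest()]).
#' @param crop Crop size.
#' @param format Slice format per patient directory.
#' @return A bag tibble with `slices` list-column.
#' @export
load_manifest_bags <- function(manifest_path, crop = 224L,
                               format = c("png", "dicom")) {
  format <- match.arg(format)
  man <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  dplyr::bind_rows(lapply(seq_len(nrow(man)), function(i) {
    dir <- man$slice_dir[i]
    if (!dir.exists(dir)) dir <- file.path(base, man$slice_dir[i])
    preprocess_volume(dir, man$patient_id[i], man$label[i], crop, format)
  }))
}
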