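# Minimal single-frame DICOM I/O.
#
# Only uncompressed little-endian transfer syntaxes (explicit and implicit VR)
# with monochrome single-frame pixel data are supported — the common case for
# an exported T2 series. No installed R package reads DICOM in this stack, so
# the subset needed by `dicom_to_slices()` is implemented here; anything
# outside it fails loudly rather than guessing.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"

uint16_le <- function(raw2) {
  as.integer(raw2[1]) + 256L * as.integer(raw2[2])
}

uint32_le <- function(raw4) {
  as.double(raw4[1]) + 256 * as.double(raw4[2]) +
    65536 * as.double(raw4[3]) + 16777216 * as.double(raw4[4])
}

# NUL padding is dropped at the raw level; trailing spaces per the standard
dicom_string <- function(val) {
  sub(" +$", "", rawToChar(val[val != as.raw(0)]))
}

# parse a stream of data elements starting at byte offset `pos` (1-based)
parse_dicom_elements <- function(bytes, pos, explicit, stop_group = NULL) {
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  n <- length(bytes)
  while (pos + 7 <= n + 1 && pos <= n) {
    group <- uint16_le(bytes[pos:(pos + 1)])
    element <- uint16_le(bytes[(pos + 2):(pos + 3)])
    if (!is.null(stop_group) && group != stop_group) break
    pos <- pos + 4
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1)])
      pos <- pos + 2
      if (vr %in% long_vrs) {
        pos <- pos + 2  # reserved
        len <- uint32_le(bytes[pos:(pos + 3)])
        pos <- pos + 4
      } else {
        len <- uint16_le(bytes[pos:(pos + 1)])
        pos <- pos + 2
      }
    } else {
      vr <- NA_character_
      len <- uint32_le(bytes[pos:(pos + 3)])
      pos <- pos + 4
    }
    if (len == 4294967295) {
      abort_ramil(sprintf(
        "DICOM element (%04X,%04X) has undefined length; sequences are not supported.",
        group, element))
    }
    tag <- sprintf("%04X%04X", group, element)
    out[[tag]] <- list(vr = vr, value = if (len > 0) bytes[pos:(pos + len - 1)] else raw(0))
    pos <- pos + len
  }
  list(elements = out, pos = pos)
}

#' Read one single-frame DICOM slice
#'
#' Supports uncompressed little-endian transfer syntaxes only. Returns the
#' raw pixel matrix (rows x columns, unscaled) plus the geometry tags needed
#' to order a series.
#'
#' @param path Path to one DICOM file.
#' @return A list with `pixels` (integer matrix), `series_uid`,
#'   `instance_number`, `position` (length-3 numeric or `NULL`),
#'   `orientation` (length-6 numeric or `NULL`).
#' @export
read_dicom_slice <- function(path) {
  if (!file.exists(path)) abort_ramil(paste0("DICOM file not found: ", path))
  bytes <- readBin(path, "raw", file.info(path)$size)
  pos <- 1L
  syntax <- DICOM_EXPLICIT_LE
  if (length(bytes) > 132 && rawToChar(bytes[129:132]) == "DICM") {
    meta <- parse_dicom_elements(bytes, 133L, explicit = TRUE, stop_group = 2L)
    ts <- meta$elements[["00020010"]]
    if (!is.null(ts)) syntax <- dicom_string(ts$value)
    pos <- meta$pos
  }
  if (!syntax %in% c(DICOM_EXPLICIT_LE, DICOM_IMPLICIT_LE)) {
    abort_ramil(paste0("unsupported DICOM transfer syntax: ", syntax))
  }
  parsed <- parse_dicom_elements(bytes, pos, explicit = syntax == DICOM_EXPLICIT_LE)
  el <- parsed$elements
  need <- function(tag, what) {
    if (is.null(el[[tag]])) abort_ramil(paste0("DICOM tag missing (", what, "): ", path))
    el[[tag]]
  }
  rows <- uint16_le(need("00280010", "Rows")$value)
  cols <- uint16_le(need("00280011", "Columns")$value)
  bits <- uint16_le(need("00280100", "BitsAllocated")$value)
  signed <- !is.null(el[["00280103"]]) && uint16_le(el[["00280103"]]$value) == 1L
  px_raw <- need("7FE00010", "PixelData")$value
  size <- bits %/% 8L
  vals <- readBin(px_raw, "integer", n = rows * cols, size = size,
                  signed = signed, endian = "little")
  num_tag <- function(tag) {
    if (is.null(el[[tag]])) return(NULL)
    as.numeric(strsplit(dicom_string(el[[tag]]$value), "\\\\")[[1]])
  }
  list(
    pixels = t(matrix(vals, nrow = cols, ncol = rows)),  # DICOM stores row-major
    series_uid = if (!is.null(el[["0020000E"]])) dicom_string(el[["0020000E"]]$value) else NA_character_,
    instance_number = if (!is.null(el[["00200013"]])) {
      as.integer(dicom_string(el[["00200013"]]$value))
    } else NA_integer_,
    position = num_tag("00200032"),
    orientation = num_tag("00200037")
  )
}

# pad a string value to even length: NUL for UIDs, space otherwise
pad_even_raw <- function(s, vr) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) {
    r <- c(r, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  r
}

raw_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dicom_element <- function(group, element, vr, value_raw) {
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  head <- c(raw_uint16(group), raw_uint16(element), charToRaw(vr))
  if (vr %in% long_vrs) {
    c(head, as.raw(c(0, 0)), raw_uint32(length(value_raw)), value_raw)
  } else {
    c(head, raw_uint16(length(value_raw)), value_raw)
  }
}

dicom_str_element <- function(group, element, vr, s) {
  dicom_element(group, element, vr, pad_even_raw(s, vr))
}

#' Write a synthetic single-frame DICOM slice
#'
#' Writes a minimal explicit-VR little-endian monochrome file: enough for
#' round-trip testing of [dicom_to_slices()] and for building synthetic
#' series. Not a general-purpose DICOM writer.
#'
#' @param pixels Numeric matrix in `[0, 1]` or integer matrix; numeric input
#'   is scaled to the full 16-bit range.
#' @param path Output path.
#' @param series_uid,instance_number Series identity and ordering tags.
#' @param position Length-3 ImagePositionPatient (or `NULL` to omit).
#' @param orientation Length-6 ImageOrientationPatient row/column cosines.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(pixels, path,
                              series_uid = "1.2.826.0.1.3680043.9999.1",
                              instance_number = 1L,
                              position = c(0, 0, 0),
                              orientation = c(1, 0, 0, 0, 1, 0)) {
  if (is.double(pixels)) {
    pixels <- matrix(as.integer(round(clamp(pixels, 0, 1) * 65535)),
                     nrow(pixels), ncol(pixels))
  }
  rows <- nrow(pixels)
  cols <- ncol(pixels)
  # pixel data row-major, unsigned 16-bit
  vals <- as.integer(t(pixels))
  px <- writeBin(ifelse(vals > 32767L, vals - 65536L, vals),
                 raw(), size = 2, endian = "little")
  ds <- c(
    dicom_str_element(0x0008, 0x0018, "UI",
                      paste0(series_uid, ".", instance_number)),
    dicom_str_element(0x0008, 0x0060, "CS", "MR"),
    dicom_str_element(0x0020, 0x000E, "UI", series_uid),
    dicom_str_element(0x0020, 0x0013, "IS", as.character(instance_number))
  )
  if (!is.null(position)) {
    ds <- c(ds, dicom_str_element(0x0020, 0x0032, "DS",
                                  paste(format(position, trim = TRUE), collapse = "\\")))
  }
  if (!is.null(orientation)) {
    ds <- c(ds, dicom_str_element(0x0020, 0x0037, "DS",
                                  paste(format(orientation, trim = TRUE), collapse = "\\")))
  }
  ds <- c(
    ds,
    dicom_element(0x0028, 0x0002, "US", raw_uint16(1)),
    dicom_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dicom_element(0x0028, 0x0010, "US", raw_uint16(rows)),
    dicom_element(0x0028, 0x0011, "US", raw_uint16(cols)),
    dicom_element(0x0028, 0x0100, "US", raw_uint16(16)),
    dicom_element(0x0028, 0x0101, "US", raw_uint16(16)),
    dicom_element(0x0028, 0x0102, "US", raw_uint16(15)),
    dicom_element(0x0028, 0x0103, "US", raw_uint16(0)),
    dicom_element(0x7FE0, 0x0010, "OW", px)
  )
  meta_body <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_str_element(0x0002, 0x0010, "UI", DICOM_EXPLICIT_LE)
  )
  meta <- c(dicom_element(0x0002, 0x0000, "UL", raw_uint32(length(meta_body))),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}
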