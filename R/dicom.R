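# Minimal DICOM codec for single-frame, uncompressed CT slices
# (implicit/explicit VR little endian). Covers exactly what the pipeline
# needs: pixel data with rescale tags, geometry (position, spacing,
# thickness, instance number) and the four metadata fields kept in the
# antemortem database (patient ID, birth date, sex, study date). Not a
# general DICOM implementation: no sequences with undefined length, no
# compressed transfer syntaxes, no multi-frame objects.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"

SHORT_VRS <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
               "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL",
               "US")

tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

# ---- reading ---------------------------------------------------------------

#' Read one DICOM file
#'
#' Parses a single-frame little-endian DICOM file into a named list of
#' elements (keyed "GGGG,EEEE"). Pixel data is decoded to an integer matrix
#' of stored values (no rescale applied here).
#'
#' @param path file path.
#' @return list with `elements` (named list) and `pixels` (matrix or NULL).
#' @keywords internal
dicom_read_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) stop("not a DICOM file (too short): ", path)
  pos <- 1L
  if (length(raw) >= 132L &&
      rawToChar(raw[129:132]) == "DICM") pos <- 133L
  explicit <- TRUE
  elements <- list()
  pixels <- NULL
  syntax <- UID_EXPLICIT_LE
  n <- length(raw)
  in_meta <- TRUE
  while (pos + 7L <= n) {
    group <- readBin(raw[pos:(pos + 1L)], "integer", size = 2L,
                     endian = "little", signed = FALSE)
    element <- readBin(raw[(pos + 2L):(pos + 3L)], "integer", size = 2L,
                       endian = "little", signed = FALSE)
    if (in_meta && group != 2L) {
      # meta group (always explicit) ends; switch to the dataset syntax
      in_meta <- FALSE
      explicit <- !identical(syntax, UID_IMPLICIT_LE)
      if (!syntax %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE))
        stop("unsupported transfer syntax ", syntax, " in ", path)
    }
    pos <- pos + 4L
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% SHORT_VRS) {
        len <- readBin(raw[(pos + 2L):(pos + 3L)], "integer", size = 2L,
                       endian = "little", signed = FALSE)
        pos <- pos + 4L
      } else {
        len <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                       endian = "little")
        pos <- pos + 8L
      }
    } else {
      vr <- NA_character_
      len <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L,
                     endian = "little")
      pos <- pos + 4L
    }
    if (len < 0L || len == -1L)
      stop("undefined-length element not supported in ", path)
    if (pos + len - 1L > n)
      stop("truncated DICOM element in ", path)
    val <- if (len > 0L) raw[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- tag_key(group, element)
    if (group == 0x7FE0L && element == 0x0010L) {
      elements[[key]] <- TRUE   # presence marker; decoded below
      pix_raw <- val
    } else {
      elements[[key]] <- decode_value(val, vr, group, element)
      if (key == "0002,0010") syntax <- elements[[key]]
    }
  }
  if (exists("pix_raw", inherits = FALSE)) {
    rows <- elements[["0028,0010"]]
    cols <- elements[["0028,0011"]]
    bits <- elements[["0028,0100"]] %||% 16L
    signed <- (elements[["0028,0103"]] %||% 0L) == 1L
    if (is.null(rows) || is.null(cols))
      stop("pixel data without Rows/Columns in ", path)
    size <- bits %/% 8L
    v <- readBin(pix_raw, "integer", n = rows * cols, size = size,
                 endian = "little", signed = if (size == 1L) FALSE else signed)
    if (!signed && size == 2L) v <- ifelse(v < 0L, v + 65536L, v)
    pixels <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  }
  list(elements = elements, pixels = pixels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

decode_value <- function(val, vr, group, element) {
  if (is.na(vr)) vr <- implicit_vr(group, element)
  switch(vr,
    US = readBin(val, "integer", n = length(val) %/% 2L, size = 2L,
                 endian = "little", signed = FALSE),
    UL = readBin(val, "integer", n = length(val) %/% 4L, size = 4L,
                 endian = "little"),
    SS = readBin(val, "integer", n = length(val) %/% 2L, size = 2L,
                 endian = "little", signed = TRUE),
    DS = as.numeric(strsplit(trimws(rawToChar(val)), "\\\\")[[1]]),
    IS = as.integer(strsplit(trimws(rawToChar(val)), "\\\\")[[1]]),
    FD = readBin(val, "double", n = length(val) %/% 8L, size = 8L,
                 endian = "little"),
    OB = val,
    UN = val,
    {
      s <- rawToChar(val[val != as.raw(0)])
      trimws(s)
    })
}

# VR lookup for the implicit syntax, restricted to the tags this codec uses.
implicit_vr <- function(group, element) {
  key <- tag_key(group, element)
  us_tags <- c("0028,0002", "0028,0010", "0028,0011", "0028,0100",
               "0028,0101", "0028,0102", "0028,0103")
  ds_tags <- c("0018,0050", "0020,0032", "0020,0037", "0028,0030",
               "0028,1052", "0028,1053")
  if (key %in% us_tags) return("US")
  if (key %in% ds_tags) return("DS")
  if (key == "0020,0013") return("IS")
  "LO"
}

# ---- writing ---------------------------------------------------------------

encode_element <- function(group, element, vr, val) {
  bytes <- switch(vr,
    US = writeBin(as.integer(val), raw(), size = 2L, endian = "little"),
    UL = writeBin(as.integer(val), raw(), size = 4L, endian = "little"),
    OB = as.raw(val),
    OW = val,
    {
      s <- if (vr %in% c("DS", "IS"))
        paste(vapply(val, format_ds, ""), collapse = "\\")
      else paste(val, collapse = "\\")
      charToRaw(s)
    })
  if (length(bytes) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    bytes <- c(bytes, pad)
  }
  head <- c(writeBin(as.integer(group), raw(), size = 2L, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2L, endian = "little"))
  if (vr %in% SHORT_VRS) {
    c(head, charToRaw(vr),
      writeBin(length(bytes), raw(), size = 2L, endian = "little"), bytes)
  } else {
    c(head, charToRaw(vr), as.raw(c(0L, 0L)),
      writeBin(length(bytes), raw(), size = 4L, endian = "little"), bytes)
  }
}

format_ds <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE, digits = 10)
  if (nchar(s) > 16L) s <- substr(s, 1L, 16L)
  s
}

#' Write a single-frame CT DICOM file
#'
#' Explicit VR little endian; pixel values are converted to stored values
#' with `stored = (pixels - rescale_intercept) / rescale_slope`, rounded,
#' and written as signed 16-bit integers.
#'
#' @param path output file path.
#' @param pixels numeric matrix of pixel values (e.g. HU).
#' @param patient_id,birth_date,sex,study_date metadata; `birth_date` may be
#'   `NA`/`NULL` (tag omitted), `sex` one of `"F"`, `"M"`, `""`
#'   or `NULL` (tag omitted). Dates are "YYYYMMDD" strings.
#' @param series_uid,sop_uid,study_uid DICOM UIDs (plain unique strings).
#' @param instance_number 1-based instance number.
#' @param z_position slice position along the scan axis in mm.
#' @param pixel_spacing_mm length-2 (row, column) spacing in mm.
#' @param slice_thickness_mm slice thickness in mm.
#' @param rescale_intercept,rescale_slope rescale tags.
#' @return `path`, invisibly.
#' @export
dicom_write_slice <- function(path, pixels,
                              patient_id, study_date,
                              birth_date = NULL, sex = NULL,
                              series_uid, sop_uid,
                              study_uid = paste0(series_uid, ".0"),
                              instance_number = 1L, z_position = 0,
                              pixel_spacing_mm = c(1, 1),
                              slice_thickness_mm = 1,
                              rescale_intercept = 0, rescale_slope = 1) {
  stopifnot(is.matrix(pixels))
  stored <- round_half_up((pixels - rescale_intercept) / rescale_slope)
  if (any(stored < -32768 | stored > 32767))
    stop("stored pixel values exceed the signed 16-bit range", call. = FALSE)
  pix_raw <- writeBin(as.integer(t(stored)), raw(), size = 2L,
                      endian = "little")

  meta <- c(
    encode_element(0x0002, 0x0001, "OB", c(0L, 1L)),
    encode_element(0x0002, 0x0002, "UI", UID_CT_STORAGE),
    encode_element(0x0002, 0x0003, "UI", sop_uid),
    encode_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE))
  meta <- c(encode_element(0x0002, 0x0000, "UL", length(meta)), meta)

  body <- c(
    encode_element(0x0008, 0x0016, "UI", UID_CT_STORAGE),
    encode_element(0x0008, 0x0018, "UI", sop_uid),
    encode_element(0x0008, 0x0020, "DA", study_date),
    encode_element(0x0008, 0x0060, "CS", "CT"),
    encode_element(0x0010, 0x0020, "LO", patient_id))
  if (!is.null(birth_date) && !is.na(birth_date))
    body <- c(body, encode_element(0x0010, 0x0030, "DA", birth_date))
  if (!is.null(sex) && !is.na(sex))
    body <- c(body, encode_element(0x0010, 0x0040, "CS", sex))
  body <- c(body,
    encode_element(0x0018, 0x0050, "DS", slice_thickness_mm),
    encode_element(0x0020, 0x000D, "UI", study_uid),
    encode_element(0x0020, 0x000E, "UI", series_uid),
    encode_element(0x0020, 0x0013, "IS", as.integer(instance_number)),
    encode_element(0x0020, 0x0032, "DS", c(0, 0, z_position)),
    encode_element(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    encode_element(0x0028, 0x0002, "US", 1L),
    encode_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    encode_element(0x0028, 0x0010, "US", nrow(pixels)),
    encode_element(0x0028, 0x0011, "US", ncol(pixels)),
    encode_element(0x0028, 0x0030, "DS", pixel_spacing_mm),
    encode_element(0x0028, 0x0100, "US", 16L),
    encode_element(0x0028, 0x0101, "US", 16L),
    encode_element(0x0028, 0x0102, "US", 15L),
    encode_element(0x0028, 0x0103, "US", 1L),
    encode_element(0x0028, 0x1052, "DS", rescale_intercept),
    encode_element(0x0028, 0x1053, "DS", rescale_slope),
    encode_element(0x7FE0, 0x0010, "OW", pix_raw))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
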