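# Reading CT slices and identity metadata into the pipeline's internal
# representation. DICOM series come through the built-in codec (dicom.R);
# plain PNG/TIFF grayscale images are supported for tests and ad-hoc use.
# Coordinate convention: 0-based pixel indices, x = column, y = row, origin
# top-left.

#' Construct a slice image
#'
#' @param pixels non-empty numeric matrix of intensities (HU after rescale,
#'   or raw grayscale for non-DICOM input).
#' @param pixel_spacing_mm length-2 positive (row, column) spacing in mm.
#' @param slice_thickness_mm positive slice thickness in mm.
#' @param slice_index 0-based position in the stack.
#' @param series_id opaque series identifier.
#' @return object of class `slice_image`.
#' @export
slice_image <- function(pixels, pixel_spacing_mm = c(1, 1),
                        slice_thickness_mm = 1, slice_index = 0L,
                        series_id = "") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty rectangular matrix", call. = FALSE)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stop("`pixel_spacing_mm` must be two positive values", call. = FALSE)
  if (slice_thickness_mm <= 0)
    stop("`slice_thickness_mm` must be positive", call. = FALSE)
  if (slice_index < 0)
    stop("`slice_index` must be non-negative", call. = FALSE)
  structure(list(pixels = pixels,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 slice_index = as.integer(slice_index),
                 series_id = as.character(series_id)),
            class = "slice_image")
}

#' Construct slice metadata
#'
#' An absent DICOM sex tag (or any value other than F/M) maps to
#' `"unknown"`; dates are "YYYYMMDD" strings or `NA`.
#'
#' @param patient_id_raw raw patient identifier (pseudonymised later, never
#'   stored in a database).
#' @param study_date study date string.
#' @param birth_date birth date string or `NA`.
#' @param sex one of `"female"`, `"male"`, `"unknown"`.
#' @param modality modality string (e.g. "CT").
#' @return object of class `slice_metadata`.
#' @export
slice_metadata <- function(patient_id_raw, study_date, birth_date = NA,
                           sex = "unknown", modality = "CT") {
  sex <- as.character(sex)
  if (!sex %in% c("female", "male", "unknown"))
    stop("`sex` must be one of female/male/unknown", call. = FALSE)
  structure(list(patient_id_raw = as.character(patient_id_raw),
                 study_date = as.character(study_date),
                 birth_date = if (is.null(birth_date)) NA_character_
                              else as.character(birth_date),
                 sex = sex,
                 modality = as.character(modality)),
            class = "slice_metadata")
}

normalize_sex <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return("unknown")
  switch(toupper(trimws(x)), F = "female", M = "male", "unknown")
}

#' Read a DICOM series
#'
#' Reads every DICOM file in `path` (a directory or an explicit file list),
#' applies the rescale slope/intercept to obtain HU, and returns the slices
#' ordered by spatial position along the scan axis (falling back to
#' InstanceNumber, then file name). `slice_index` is assigned 0..n-1 in that
#' order.
#'
#' @param path directory containing one series, or a character vector of
#'   file paths.
#' @return list of `list(image = slice_image, metadata = slice_metadata)`,
#'   one per slice, in stack order.
#' @export
read_dicom_series <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, full.names = TRUE) else path
  files <- files[file.exists(files) & !dir.exists(files)]
  if (length(files) == 0L)
    stop("no readable files in input", call. = FALSE)
  parsed <- list()
  for (f in files) {
    d <- tryCatch(dicom_read_file(f), error = function(e) e)
    if (inherits(d, "error")) {
      warning("skipping unreadable file ", f, ": ", conditionMessage(d))
      next
    }
    if (is.null(d$pixels))
      stop("DICOM file has no pixel data: ", f, call. = FALSE)
    d$file <- f
    parsed[[length(parsed) + 1L]] <- d
  }
  if (length(parsed) == 0L)
    stop("no readable DICOM files in input", call. = FALSE)
  series_ids <- vapply(parsed, function(d)
    d$elements[["0020,000E"]] %||% "", "")
  if (length(unique(series_ids)) > 1L)
    stop("mixed series identifiers in one call: ",
         paste(unique(series_ids), collapse = ", "), call. = FALSE)

  zpos <- vapply(parsed, function(d) {
    p <- d$elements[["0020,0032"]]
    if (is.null(p) || length(p) < 3L) NA_real_ else p[3]
  }, 0)
  inst <- vapply(parsed, function(d) {
    v <- d$elements[["0020,0013"]]
    if (is.null(v)) NA_real_ else as.numeric(v[1])
  }, 0)
  ord <- if (!anyNA(zpos)) order(zpos, vapply(parsed, `[[`, "", "file"))
         else if (!anyNA(inst)) order(inst, vapply(parsed, `[[`, "", "file"))
         else order(vapply(parsed, `[[`, "", "file"))
  parsed <- parsed[ord]

  lapply(seq_along(parsed), function(i) {
    d <- parsed[[i]]
    el <- d$elements
    slope <- (el[["0028,1053"]] %||% 1)[1]
    intercept <- (el[["0028,1052"]] %||% 0)[1]
    px <- d$pixels * slope + intercept
    spacing <- el[["0028,0030"]] %||% c(1, 1)
    thick <- (el[["0018,0050"]] %||% 1)[1]
    list(
      image = slice_image(px,
                          pixel_spacing_mm = spacing,
                          slice_thickness_mm = thick,
                          slice_index = i - 1L,
                          series_id = el[["0020,000E"]] %||% ""),
      metadata = slice_metadata(
        patient_id_raw = el[["0010,0020"]] %||% "",
        study_date = el[["0008,0020"]] %||% NA,
        birth_date = el[["0010,0030"]] %||% NA,
        sex = normalize_sex(el[["0010,0040"]]),
        modality = el[["0008,0060"]] %||% "CT"))
  })
}

#' Read a plain grayscale image as a slice
#'
#' 8/16-bit PNG or TIFF, rescaled to 0..255 (PNG/TIFF values come back in
#' \[0, 1\]). Multi-channel images use the first channel.
#'
#' @param path image file path.
#' @param pixel_spacing_mm,slice_thickness_mm geometry to attach (defaults
#'   1 mm).
#' @return a [slice_image()].
#' @export
read_image_file <- function(path, pixel_spacing_mm = c(1, 1),
                            slice_thickness_mm = 1) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  slice_image(arr * 255,
              pixel_spacing_mm = pixel_spacing_mm,
              slice_thickness_mm = slice_thickness_mm,
              slice_index = 0L,
              series_id = basename(path))
}
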