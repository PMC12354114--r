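# The antemortem CV database: one entry per antemortem CT slice holding the
# slice's feature set and pseudonymised identity metadata -- never pixel
# data, never the raw patient ID. Persisted in a small versioned binary
# container (JSON header + contiguous double blocks), optionally encrypted
# with authenticated AES-256-GCM.

CVDB_MAGIC <- "CVDB"
CVDB_VERSION <- 1L

#' Pseudonymize a patient identifier
#'
#' Keyed one-way digest (HMAC-SHA256). The same (id, key) always maps to
#' the same identity key; without the key the raw ID cannot be recovered,
#' so re-identification is only possible at the institution holding the
#' key.
#'
#' @param patient_id_raw non-empty raw identifier.
#' @param key non-empty secret key string.
#' @return character identity key (hex digest).
#' @export
pseudonymize <- function(patient_id_raw, key) {
  if (is.null(key) || !nzchar(key))
    stop("pseudonymization key must be non-empty", call. = FALSE)
  if (is.null(patient_id_raw) || !nzchar(patient_id_raw))
    stop("patient id must be non-empty", call. = FALSE)
  unclass(as.character(openssl::sha256(charToRaw(patient_id_raw),
                                       key = charToRaw(key))))
}

new_cvdatabase <- function(entries, params_fingerprint, provenance = "") {
  ids <- vapply(entries, `[[`, "", "identity_id")
  structure(list(entries = entries,
                 identity_index = split(seq_along(entries), ids),
                 params_fingerprint = params_fingerprint,
                 provenance = provenance),
            class = "cvdatabase")
}

#' @export
print.cvdatabase <- function(x, ...) {
  cat(sprintf("<cvdatabase: %d entries, %d identities, fingerprint %s...>\n",
              length(x$entries), length(x$identity_index),
              substr(x$params_fingerprint, 1, 8)))
  invisible(x)
}

#' Number of entries and identities
#' @param db a `cvdatabase`.
#' @return named integer vector.
#' @export
db_counts <- function(db) {
  c(entries = length(db$entries),
    identities = length(db$identity_index),
    exams = length(unique(vapply(db$entries, `[[`, "", "exam_id"))))
}

#' Build the antemortem CV database
#'
#' Processes every slice of every readable series: preprocessing, feature
#' extraction, and storage of the feature set together with pseudonymised
#' metadata. Complete series are enrolled (no slice filtering). Unreadable
#' series are skipped with a warning; images themselves are never stored.
#'
#' @param series_sources character vector of DICOM series directories.
#' @param preprocess a [preprocess_params()] object.
#' @param akaze an [akaze_params()] object.
#' @param key pseudonymisation secret.
#' @return a `cvdatabase`.
#' @export
build_database <- function(series_sources,
                           preprocess = preprocess_params(),
                           akaze = akaze_params(),
                           key) {
  entries <- list()
  skipped <- 0L
  for (src in series_sources) {
    slices <- tryCatch(read_dicom_series(src), error = function(e) e)
    if (inherits(slices, "error")) {
      warning("skipping series ", src, ": ", conditionMessage(slices))
      skipped <- skipped + 1L
      next
    }
    for (sl in slices) {
      entries[[length(entries) + 1L]] <-
        make_entry(sl$image, sl$metadata, preprocess, akaze, key)
    }
  }
  if (length(entries) == 0L)
    stop("no readable slices in any input series", call. = FALSE)
  prov <- sprintf("built %d entries from %d series (%d skipped)",
                  length(entries), length(series_sources) - skipped, skipped)
  new_cvdatabase(entries, params_fingerprint(preprocess, akaze), prov)
}

# One database entry from an in-memory slice (also used to enroll phantom
# stacks without a DICOM round trip).
make_entry <- function(image, metadata, preprocess, akaze, key) {
  fs <- extract_features(preprocess_slice(image, preprocess), akaze,
                         source_ref = list(series = image$series_id,
                                           slice_index = image$slice_index))
  identity_id <- pseudonymize(metadata$patient_id_raw, key)
  exam_id <- pseudonymize(paste0("exam:", image$series_id), key)
  list(entry_id = sprintf("%s:%03d", substr(exam_id, 1, 16),
                          image$slice_index),
       identity_id = identity_id,
       exam_id = exam_id,
       slice_index = image$slice_index,
       feature_set = fs,
       study_date = metadata$study_date,
       birth_date = metadata$birth_date,
       sex = metadata$sex)
}

#' Enroll in-memory slice stacks into a database
#'
#' Convenience builder used with the phantom generator: takes the output of
#' [generate_cohort()] directly, avoiding a DICOM round trip.
#'
#' @param cohort result of [generate_cohort()].
#' @param preprocess,akaze,key as in [build_database()].
#' @return a `cvdatabase`.
#' @export
build_database_from_cohort <- function(cohort,
                                       preprocess = preprocess_params(),
                                       akaze = akaze_params(),
                                       key = "cohort-key") {
  entries <- list()
  for (i in seq_along(cohort$identities)) {
    md <- slice_metadata(patient_id_raw = cohort$metadata$patient_id[i],
                         study_date = cohort$metadata$study_date[i],
                         birth_date = cohort$metadata$birth_date[i],
                         sex = normalize_sex(cohort$metadata$sex[i]))
    for (img in cohort$stacks[[i]]) {
      entries[[length(entries) + 1L]] <-
        make_entry(img, md, preprocess, akaze, key)
    }
  }
  new_cvdatabase(entries, params_fingerprint(preprocess, akaze),
                 sprintf("built %d entries from synthetic cohort",
                         length(entries)))
}

# ---- persistence -----------------------------------------------------------

serialize_db <- function(db) {
  ent <- db$entries
  header <- list(
    version = CVDB_VERSION,
    params_fingerprint = db$params_fingerprint,
    provenance = db$provenance,
    n_entries = length(ent),
    keypoint_cols = c("x", "y", "scale", "orientation", "response"),
    entries = lapply(ent, function(e)
      list(entry_id = e$entry_id, identity_id = e$identity_id,
           exam_id = e$exam_id, slice_index = e$slice_index,
           study_date = e$study_date, birth_date = e$birth_date,
           sex = e$sex, n = e$feature_set$n,
           d = ncol(e$feature_set$descriptors))))
  hj <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, null = "null",
                                   na = "null"))
  blocks <- lapply(ent, function(e) {
    fs <- e$feature_set
    c(as.numeric(as.matrix(fs$keypoints[, c("x", "y", "scale",
                                            "orientation", "response")])),
      as.numeric(fs$descriptors))
  })
  blk <- unlist(blocks, use.names = FALSE) %||% numeric(0)
  c(writeBin(length(hj), raw(), size = 4L, endian = "little"),
    hj,
    writeBin(blk, raw(), size = 8L, endian = "little"))
}

deserialize_db <- function(payload) {
  hlen <- readBin(payload[1:4], "integer", size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(payload[5:(4L + hlen)]),
                               simplifyVector = FALSE)
  if (is.null(header$params_fingerprint))
    stop("database file is missing the `params_fingerprint` field",
         call. = FALSE)
  if (!identical(as.integer(header$version), CVDB_VERSION))
    stop("unsupported database format version ", header$version,
         " (this build reads version ", CVDB_VERSION, ")", call. = FALSE)
  doubles <- readBin(payload[-seq_len(4L + hlen)], "double",
                     n = (length(payload) - 4L - hlen) %/% 8L,
                     size = 8L, endian = "little")
  pos <- 0L
  entries <- lapply(header$entries, function(h) {
    n <- h$n; d <- h$d
    kp_vals <- doubles[pos + seq_len(n * 5L)]
    pos <<- pos + n * 5L
    dvals <- doubles[pos + seq_len(n * d)]
    pos <<- pos + n * d
    kp <- as.data.frame(matrix(kp_vals, n, 5L))
    names(kp) <- c("x", "y", "scale", "orientation", "response")
    list(entry_id = h$entry_id, identity_id = h$identity_id,
         exam_id = h$exam_id, slice_index = h$slice_index,
         feature_set = feature_set(kp, matrix(dvals, n, d)),
         study_date = h$study_date,
         birth_date = if (is.null(h$birth_date)) NA_character_
                      else h$birth_date,
         sex = h$sex)
  })
  new_cvdatabase(entries, header$params_fingerprint,
                 header$provenance %||% "")
}

# Independent keys for encryption and authentication, derived from the
# user secret by domain separation.
db_enc_key <- function(key) {
  as.vector(openssl::sha256(charToRaw(paste0("enc:", key))))
}
db_auth_tag <- function(key, data) {
  as.vector(openssl::sha256(data, key = charToRaw(paste0("mac:", key))))
}

#' Save a CV database
#'
#' Writes the versioned container; with a key, the payload is encrypted
#' with an authenticated encrypt-then-MAC scheme (AES-256-CTR plus
#' HMAC-SHA256 over the IV and ciphertext): any tampering or a wrong key
#' fails the integrity check on load. Without a key the payload is
#' plaintext (test mode).
#'
#' @param db a `cvdatabase`.
#' @param path output file.
#' @param key optional encryption secret.
#' @return `path`, invisibly.
#' @export
save_database <- function(db, path, key = NULL) {
  stopifnot(inherits(db, "cvdatabase"))
  payload <- serialize_db(db)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot write database file ", path, ": ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeBin(charToRaw(CVDB_MAGIC), con)
  writeBin(CVDB_VERSION, con, size = 4L, endian = "little")
  if (is.null(key)) {
    writeBin(0L, con, size = 1L)
    writeBin(payload, con)
  } else {
    # encrypt-then-MAC: AES-256-CTR, then HMAC-SHA256 over iv || ciphertext
    writeBin(1L, con, size = 1L)
    iv <- as.vector(openssl::rand_bytes(16L))
    ct <- as.vector(openssl::aes_ctr_encrypt(payload, key = db_enc_key(key),
                                             iv = iv))
    tag <- db_auth_tag(key, c(iv, ct))
    writeBin(iv, con)
    writeBin(tag, con)
    writeBin(ct, con)
  }
  invisible(path)
}

#' Load a CV database
#'
#' Inverse of [save_database()]; verifies the format version and the
#' presence of the parameter fingerprint. For encrypted files, a wrong key
#' or a tampered byte raises an authentication error and no partial data is
#' returned.
#'
#' @param path file written by [save_database()].
#' @param key secret for encrypted files.
#' @return a `cvdatabase`.
#' @export
load_database <- function(path, key = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 9L || rawToChar(raw[1:4]) != CVDB_MAGIC)
    stop("not a CV database file: ", path, call. = FALSE)
  version <- readBin(raw[5:8], "integer", size = 4L, endian = "little")
  if (version != CVDB_VERSION)
    stop("unsupported database format version ", version,
         " (this build reads version ", CVDB_VERSION, ")", call. = FALSE)
  encrypted <- as.integer(raw[9]) == 1L
  body <- raw[-seq_len(9L)]
  if (encrypted) {
    if (is.null(key))
      stop("database is encrypted; a key is required", call. = FALSE)
    if (length(body) < 48L)
      stop("truncated encrypted database file", call. = FALSE)
    iv <- body[1:16]
    tag <- body[17:48]
    ct <- body[-seq_len(48L)]
    if (!identical(db_auth_tag(key, c(iv, ct)), tag))
      stop("database authentication failed (wrong key or tampered file)",
           call. = FALSE)
    payload <- as.vector(openssl::aes_ctr_decrypt(ct, key = db_enc_key(key),
                                                  iv = iv))
  } else {
    payload <- body
  }
  deserialize_db(payload)
}

#' Export database metadata as CSV
#'
#' One row per entry: entry_id, identity_id, exam_id, slice_index,
#' n_features. Contains no raw identifiers and no descriptors.
#'
#' @param db a `cvdatabase`.
#' @param path output CSV path.
#' @return the data frame, invisibly.
#' @export
export_metadata_csv <- function(db, path) {
  df <- data.frame(
    entry_id = vapply(db$entries, `[[`, "", "entry_id"),
    identity_id = vapply(db$entries, `[[`, "", "identity_id"),
    exam_id = vapply(db$entries, `[[`, "", "exam_id"),
    slice_index = vapply(db$entries, `[[`, 0L, "slice_index"),
    n_features = vapply(db$entries, function(e) e$feature_set$n, 0L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Check a database's parameter fingerprint against the current config
#'
#' Querying a database built with different preprocessing or detector
#' parameters produces incomparable scores; this guard warns (or errors)
#' when the fingerprints differ.
#'
#' @param db a `cvdatabase`.
#' @param preprocess,akaze current parameter objects.
#' @param action `"warn"` (default) or `"error"`.
#' @return TRUE invisibly when fingerprints match.
#' @export
check_params_fingerprint <- function(db, preprocess, akaze,
                                     action = c("warn", "error")) {
  action <- match.arg(action)
  fp <- params_fingerprint(preprocess, akaze)
  if (!identical(fp, db$params_fingerprint)) {
    msg <- "database was built with a different parameter configuration"
    if (action == "warn") warning(msg, call. = FALSE) else
      stop(msg, call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
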