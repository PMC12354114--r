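# Small cohorts (48-64 px slices) keep feature extraction fast; the
# database logic is independent of image size.

small_cohort <- function() {
  fixture("small_cohort_db", {
    d <- file.path(tempdir(), "small-cohort")
    cohort <- generate_cohort(3, slices_per_series = 5, seed = 3, size = 48,
                              out_dir = d)
    list(cohort = cohort, dir = d)
  })
}

test_that("pseudonymization is a deterministic keyed one-way digest", {
  a1 <- pseudonymize("PAT-001", "key-A")
  a2 <- pseudonymize("PAT-001", "key-A")
  b <- pseudonymize("PAT-002", "key-A")
  c <- pseudonymize("PAT-001", "key-B")
  expect_identical(a1, a2)
  expect_false(a1 == b)
  expect_false(a1 == c)
  expect_false(grepl("PAT", a1))
  expect_error(pseudonymize("PAT-001", ""), "key")
  expect_error(pseudonymize("", "key"), "patient id")
})

test_that("building enrolls every slice of every series", {
  sc <- small_cohort()
  suppressWarnings(
    db <- build_database(sc$cohort$dirs, key = "build-key"))
  counts <- db_counts(db)
  expect_equal(counts[["entries"]], 15L)      # 3 identities x 5 slices
  expect_equal(counts[["identities"]], 3L)
  expect_equal(counts[["exams"]], 3L)
  # identity_index covers every entry exactly once
  expect_setequal(unlist(db$identity_index), seq_len(15L))
  expect_equal(vapply(db$entries, `[[`, 0L, "slice_index"),
               rep(0:4, times = 3))
})

test_that("two exams of one patient share an identity key", {
  sc <- small_cohort()
  d2 <- withr::local_tempdir()
  # second series for the first identity: same patient ID, new series UID
  id <- sc$cohort$identities[[1]]
  for (z in 0:1) {
    dicom_write_slice(file.path(d2, sprintf("s%d.dcm", z)),
                      render_slice(id, z)$pixels,
                      patient_id = sc$cohort$metadata$patient_id[1],
                      study_date = "20210101",
                      series_uid = "2.25.999",
                      sop_uid = sprintf("2.25.999.%d", z),
                      instance_number = z + 1L, z_position = z * 2.5)
  }
  db <- build_database(c(sc$cohort$dirs[1], d2), key = "build-key")
  counts <- db_counts(db)
  expect_equal(counts[["identities"]], 1L)
  expect_equal(counts[["exams"]], 2L)
  expect_equal(counts[["entries"]], 7L)
})

test_that("the parameter fingerprint tracks the configuration", {
  fp1 <- params_fingerprint(preprocess_params(), akaze_params())
  fp2 <- params_fingerprint(preprocess_params(),
                            akaze_params(detection_threshold = 0.002))
  expect_false(fp1 == fp2)
  db <- toy_database(list(random_feature_set(5)), "I1")
  expect_warning(
    check_params_fingerprint(db, preprocess_params(), akaze_params()),
    "different parameter")
  expect_error(
    check_params_fingerprint(db, preprocess_params(), akaze_params(),
                             action = "error"),
    "different parameter")
})

test_that("save/load round-trips the database losslessly", {
  sc <- small_cohort()
  db <- build_database_from_cohort(sc$cohort, key = "rt-key")
  f <- withr::local_tempfile(fileext = ".cvdb")
  save_database(db, f)
  back <- load_database(f)
  expect_equal(length(back$entries), length(db$entries))
  expect_identical(back$params_fingerprint, db$params_fingerprint)
  for (i in seq_along(db$entries)) {
    expect_identical(back$entries[[i]]$feature_set$descriptors,
                     db$entries[[i]]$feature_set$descriptors)
    expect_equal(back$entries[[i]]$feature_set$keypoints,
                 db$entries[[i]]$feature_set$keypoints)
    expect_identical(back$entries[[i]]$identity_id,
                     db$entries[[i]]$identity_id)
  }

  # empty database round trip
  empty <- sinusmatch:::new_cvdatabase(list(), "fp-empty")
  f2 <- withr::local_tempfile(fileext = ".cvdb")
  save_database(empty, f2)
  expect_equal(length(load_database(f2)$entries), 0L)
})

test_that("encryption authenticates: wrong key and tampering both fail", {
  db <- toy_database(list(random_feature_set(8), random_feature_set(6)),
                     c("I1", "I2"))
  f <- withr::local_tempfile(fileext = ".cvdb")
  save_database(db, f, key = "secret-1")
  back <- load_database(f, key = "secret-1")
  expect_identical(back$entries[[1]]$feature_set$descriptors,
                   db$entries[[1]]$feature_set$descriptors)
  expect_error(load_database(f, key = "wrong"), "authentication")
  expect_error(load_database(f), "key is required")
  # flip one payload byte
  bytes <- readBin(f, "raw", file.info(f)$size)
  bytes[length(bytes) - 5L] <- xor(bytes[length(bytes) - 5L], as.raw(1L))
  writeBin(bytes, f)
  expect_error(load_database(f, key = "secret-1"), "authentication")
})

test_that("saved databases leak neither pixels nor raw patient IDs", {
  sc <- small_cohort()
  db <- build_database(sc$cohort$dirs, key = "privacy-key")
  f <- withr::local_tempfile(fileext = ".cvdb")
  save_database(db, f)
  bytes <- readBin(f, "raw", file.info(f)$size)
  for (pid in sc$cohort$metadata$patient_id)
    expect_length(grepRaw(pid, bytes, all = TRUE), 0L)
  # entries hold feature sets and metadata only -- no image field exists
  expect_length(grepRaw("pixels", bytes, all = TRUE), 0L)
  expect_false(any(vapply(db$entries, function(e) "pixels" %in% names(e),
                          TRUE)))
})

test_that("a file missing the fingerprint field is rejected by name", {
  db <- toy_database(list(random_feature_set(3)), "I1")
  payload <- sinusmatch:::serialize_db(db)
  hlen <- readBin(payload[1:4], "integer", size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(payload[5:(4 + hlen)]),
                            simplifyVector = FALSE)
  hdr$params_fingerprint <- NULL
  hj <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE))
  doctored <- c(writeBin(length(hj), raw(), size = 4L, endian = "little"),
                hj, payload[-seq_len(4L + hlen)])
  expect_error(sinusmatch:::deserialize_db(doctored), "params_fingerprint")
})

test_that("metadata export carries no descriptors and no raw IDs", {
  sc <- small_cohort()
  db <- build_database_from_cohort(sc$cohort, key = "csv-key")
  f <- withr::local_tempfile(fileext = ".csv")
  df <- export_metadata_csv(db, f)
  expect_named(df, c("entry_id", "identity_id", "exam_id", "slice_index",
                     "n_features"))
  expect_equal(nrow(df), 15L)
  expect_false(any(grepl("PH0", readLines(f))))
})
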