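# DICOM round trips use the package's own writer: fixtures are generated at
# test time, never stored.

write_test_slice <- function(dir, pixels, z, instance, series = "2.25.77",
                             sex = "F", birth = "19500101", ...) {
  dicom_write_slice(file.path(dir, sprintf("s%02d.dcm", instance)),
                    pixels, patient_id = "PAT-001",
                    study_date = "20150601", birth_date = birth, sex = sex,
                    series_uid = series,
                    sop_uid = sprintf("%s.%d", series, instance),
                    instance_number = instance, z_position = z, ...)
}

test_that("rescale slope and intercept are applied on read", {
  d <- withr::local_tempdir()
  # stored value 1024 with intercept -1024, slope 1 => 0 HU
  px <- matrix(0, 40, 40)          # HU passed to the writer
  write_test_slice(d, px, z = 0, instance = 1,
                   rescale_intercept = -1024, rescale_slope = 1)
  slices <- read_dicom_series(d)
  expect_length(slices, 1L)
  expect_equal(slices[[1]]$image$pixels, px)
  raw <- sinusmatch:::dicom_read_file(list.files(d, full.names = TRUE)[1])
  expect_equal(raw$pixels[1, 1], 1024)   # stored value before rescale
})

test_that("absent sex tag maps to unknown and dates survive", {
  d <- withr::local_tempdir()
  write_test_slice(d, matrix(10, 32, 32), z = 0, instance = 1,
                   sex = NULL, birth = NULL)
  md <- read_dicom_series(d)[[1]]$metadata
  expect_identical(md$sex, "unknown")
  expect_true(is.na(md$birth_date))
  expect_identical(md$study_date, "20150601")
})

test_that("slices are ordered by position, not file name", {
  d <- withr::local_tempdir()
  # file names deliberately anti-correlated with z position
  for (i in 1:3) {
    dicom_write_slice(file.path(d, sprintf("z%d.dcm", 4 - i)),
                      matrix(i * 100, 32, 32), patient_id = "P",
                      study_date = "20150601", series_uid = "2.25.8",
                      sop_uid = sprintf("2.25.8.%d", i),
                      instance_number = i, z_position = i * 2.5)
  }
  slices <- read_dicom_series(d)
  expect_equal(vapply(slices, function(s) s$image$pixels[1, 1], 0),
               c(100, 200, 300))
  expect_equal(vapply(slices, function(s) s$image$slice_index, 0L), 0:2)
})

test_that("a phantom DICOM stack round-trips pixels and metadata", {
  d <- withr::local_tempdir()
  cohort <- generate_cohort(2, slices_per_series = 3, seed = 5, size = 48,
                            out_dir = d)
  slices <- read_dicom_series(cohort$dirs[1])
  expect_length(slices, 3L)
  for (z in 1:3) {
    orig <- cohort$stacks[[1]][[z]]$pixels
    got <- slices[[z]]$image$pixels
    # writer quantises to integer stored values
    expect_equal(got, sinusmatch:::round_half_up(orig))
  }
  md <- slices[[1]]$metadata
  expect_identical(md$patient_id_raw, cohort$metadata$patient_id[1])
  expect_identical(md$birth_date, cohort$metadata$birth_date[1])
  expect_equal(slices[[1]]$image$slice_thickness_mm, 2.5)
})

test_that("every readable file appears exactly once; errors are typed", {
  d <- withr::local_tempdir()
  for (i in 1:4) write_test_slice(d, matrix(i, 32, 32), z = i, instance = i)
  slices <- read_dicom_series(d)
  expect_equal(sort(vapply(slices, function(s) s$image$pixels[1, 1], 0)),
               1:4)

  expect_error(read_dicom_series(file.path(d, "missing-dir")), "no readable")

  d2 <- withr::local_tempdir()
  write_test_slice(d2, matrix(1, 32, 32), z = 0, instance = 1,
                   series = "2.25.1")
  write_test_slice(d2, matrix(1, 32, 32), z = 1, instance = 2,
                   series = "2.25.2")
  expect_error(read_dicom_series(d2), "mixed series")
})

test_that("plain grayscale images load as slices", {
  f <- withr::local_tempfile(fileext = ".png")
  m <- matrix(runif(32 * 40), 32, 40)
  png::writePNG(m, f)
  sl <- read_image_file(f)
  expect_s3_class(sl, "slice_image")
  expect_equal(dim(sl$pixels), c(32, 40))
  expect_equal(sl$pixels / 255, m, tolerance = 1 / 255)
})

test_that("slice_image validates its invariants", {
  expect_error(slice_image(matrix(1, 2, 2), slice_thickness_mm = 0),
               "positive")
  expect_error(slice_image(matrix(1, 2, 2), pixel_spacing_mm = c(1, -1)),
               "positive")
  expect_error(slice_metadata("p", "20200101", sex = "other"), "female/male")
})
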