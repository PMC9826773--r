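test_that("image_stack validates geometry and finiteness", {
  v <- array(0, dim = c(8, 8, 2))
  s <- image_stack(v, 0.5)
  expect_s3_class(s, "image_stack")
  expect_identical(dim(s), c(8L, 8L, 2L))
  expect_error(image_stack(v, -0.5), "positive")
  v[1, 1, 1] <- NaN
  expect_error(image_stack(v, 0.5), "finite")
  m <- matrix(1, 8, 8)
  expect_identical(dim(image_stack(m, 1)), c(8L, 8L, 1L))
})

test_that("mean_hu follows the pixel-center rule", {
  s <- image_stack(array(100, dim = c(64, 64, 3)), 0.5)
  roi <- circular_roi(32.5, 32.5, 10)
  expect_equal(mean_hu(s, roi), 100)
  expect_equal(mean_hu(s, roi, slice_index = 3), 100)

  # half-plane 0/200: ROI centered on the boundary averages to ~100
  v <- array(0, dim = c(64, 64, 1))
  v[, 33:64, 1] <- 200
  s2 <- image_stack(v, 0.5)
  expect_equal(mean_hu(s2, circular_roi(32.5, 32.5, 10)), 100,
               tolerance = 0.02)

  # ROI outside the image is a geometry error
  expect_error(mean_hu(s, circular_roi(2, 2, 10)), "geometry")
})

test_that("mean_hu is invariant to slice order and joint translation", {
  st <- make_disk_stack(size = 96, contrast = 42, diameter = 25)
  roi <- center_roi(st, 8)
  base <- mean_hu(st, roi)
  expect_equal(base, 42, tolerance = 1e-9)

  # translate content together with the ROI (whole pixels)
  st2 <- make_disk_stack(size = 96, contrast = 42, diameter = 25,
                         center_x = 5 * 0.488, center_y = -3 * 0.488)
  roi2 <- circular_roi(roi$center_row - 3, roi$center_col + 5, 8)
  expect_equal(mean_hu(st2, roi2), base)

  # slice ordering irrelevant for a fixed slice's content
  v <- array(rnorm(32 * 32 * 4), dim = c(32, 32, 4))
  s <- image_stack(abs(v) + 1, 1)
  sr <- image_stack(s$voxels[, , 4:1], 1)
  expect_equal(mean_hu(s, circular_roi(16, 16, 8), 2),
               mean_hu(sr, circular_roi(16, 16, 8), 3))
})

test_that("native stack round-trip preserves geometry exactly and HU to 0.5", {
  set.seed(7)
  v <- array(runif(64 * 64 * 40, -1000, 3000), dim = c(64, 64, 40))
  s <- image_stack(v, 0.488, 0.488, slice_thickness = 0.5,
                   meta = list(energy_keV = 40, version_tag = "V1"))
  path <- file.path(tempdir(), "stack_rt")
  write_stack(s, path, "native_stack")
  r <- read_stack(path, "native_stack")
  expect_identical(dim(r), dim(s))
  expect_identical(r$pixel_spacing_x, s$pixel_spacing_x)
  expect_identical(r$slice_thickness, s$slice_thickness)
  expect_lt(max(abs(r$voxels - s$voxels)), 0.5 + 1e-9)
  expect_equal(r$meta$energy_keV, 40)

  # integer HU round-trips bit-identically
  vi <- array(round(runif(32 * 32 * 2, -1000, 3000)), dim = c(32, 32, 2))
  si <- image_stack(vi, 0.5)
  write_stack(si, path, "native_stack")
  expect_identical(read_stack(path, "native_stack")$voxels, vi)

  # constant zero stack reads back as zero
  s0 <- image_stack(array(0, dim = c(64, 64, 2)), 1)
  write_stack(s0, path, "native_stack")
  expect_equal(mean(read_stack(path, "native_stack")$voxels), 0)

  expect_error(read_stack(file.path(tempdir(), "no_such_stack")), "not found")
})

test_that("DICOM series round-trips with slice sorting and rescale applied", {
  set.seed(11)
  v <- array(round(runif(32 * 48 * 5, -1000, 2000)), dim = c(32, 48, 5))
  s <- image_stack(v, pixel_spacing_x = 0.82, pixel_spacing_y = 0.82,
                   slice_thickness = 0.5, slice_increment = 0.5)
  dir <- file.path(tempdir(), "dcm_series")
  unlink(dir, recursive = TRUE)
  write_stack(s, dir, "dicom_series")
  r <- read_stack(dir, "dicom_series")
  expect_identical(dim(r), dim(s))
  expect_equal(r$voxels, s$voxels)
  expect_equal(r$pixel_spacing_x, 0.82)
  expect_equal(r$pixel_spacing_y, 0.82)

  # reading is insensitive to file order: rename to reverse lexical order
  files <- list.files(dir, full.names = TRUE)
  for (i in seq_along(files)) {
    file.rename(files[i], file.path(dir, sprintf("z_%d.dcm", length(files) - i)))
  }
  r2 <- read_stack(dir, "dicom_series")
  expect_equal(r2$voxels, s$voxels)

  # empty directory is a format error
  empty <- file.path(tempdir(), "dcm_empty")
  dir.create(empty, showWarnings = FALSE)
  expect_error(read_stack(empty, "dicom_series"), "format error")

  # mixed dimensions are rejected
  s2 <- image_stack(array(0, dim = c(16, 16, 1)), 0.82)
  write_stack(s2, file.path(tempdir(), "dcm_mixed"), "dicom_series")
  file.copy(list.files(file.path(tempdir(), "dcm_mixed"), full.names = TRUE)[1],
            file.path(dir, "alien.dcm"))
  expect_error(read_stack(dir, "dicom_series"), "mixed image dimensions")
})

test_that("square ROI extraction stays inside the image", {
  s <- image_stack(array(0, dim = c(64, 64, 1)), 0.5)
  expect_error(compute_nps_2d(s, list(square_roi(5, 32, 16))), "outside")
  expect_silent(compute_nps_2d(s, list(square_roi(32, 32, 16))))
})
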