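test_that("NIfTI volume and mask round-trips are lossless", {
  vox <- array(round(rnorm(16 * 16 * 4, 35, 10), 3), c(16, 16, 4))
  vol <- ct_volume(vox, spacing = c(0.5, 0.75, 5))
  f <- tempfile(fileext = ".nii.gz")
  write_ct(vol, f)
  back <- read_ct(f)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)

  m <- seg_mask(array(vox > 40, dim(vox)), spacing = vol$spacing)
  fm <- tempfile(fileext = ".nii.gz")
  write_mask(m, fm)
  back_m <- read_mask(fm, companion = vol)
  expect_identical(back_m$voxels, m$voxels)

  empty <- seg_mask(array(FALSE, dim(vox)), spacing = vol$spacing)
  write_mask(empty, fm)
  expect_equal(sum(read_mask(fm)$voxels), 0)
})

test_that("mask paired with a volume of different shape errors with both shapes", {
  vol <- ct_volume(array(0, c(8, 8, 2)), c(1, 1, 5))
  f <- tempfile(fileext = ".nii")
  write_mask(seg_mask(array(FALSE, c(4, 4, 2)), c(1, 1, 5)), f)
  expect_error(read_mask(f, companion = vol), "4x4x2")
})

test_that("volume invariants: spacing, finiteness, HU plausibility warning", {
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, 0, 5)), "positive")
  expect_error(ct_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 5)), "finite")
  expect_warning(v <- ct_volume(array(5000, c(2, 2, 2)), c(1, 1, 5)),
                 "plausible range")
  expect_length(v$meta$warnings, 1)
})

test_that("resampling merges and averages thin slices", {
  # constant field is invariant
  vol <- ct_volume(array(40, c(4, 4, 10)), c(1, 1, 1))
  out <- resample_thickness(vol, 5)
  expect_equal(dim(out$voxels)[3], 2)
  expect_true(all(out$voxels == 40))
  expect_equal(out$spacing[3], 5)

  # 5 x 1 mm column 10..50 -> single 5 mm slice = arithmetic mean 30
  vox <- array(0, c(2, 2, 5))
  vox[1, 1, ] <- c(10, 20, 30, 40, 50)
  out <- resample_thickness(ct_volume(vox, c(1, 1, 1)), 5)
  expect_equal(out$voxels[1, 1, 1], 30)

  # 4 x 2.5 mm -> 2 x 5 mm: explicit pairwise averaging oracle
  vox <- array(rnorm(6 * 6 * 4, 35, 8), c(6, 6, 4))
  vol <- ct_volume(vox, c(1, 1, 2.5))
  out <- resample_thickness(vol, 5)
  expect_equal(out$voxels[, , 1], (vox[, , 1] + vox[, , 2]) / 2)
  expect_equal(out$voxels[, , 2], (vox[, , 3] + vox[, , 4]) / 2)
  # HU mass conserved for the integer thickness ratio
  expect_equal(sum(out$voxels) * 5, sum(vox) * 2.5, tolerance = 1e-9)
})

test_that("resampling refuses to interpolate thicker slices thinner", {
  vol <- ct_volume(array(0, c(4, 4, 4)), c(1, 1, 7.5))
  expect_error(resample_thickness(vol, 5), "thicker")
  # already at target: returned unchanged
  vol5 <- ct_volume(array(1, c(4, 4, 4)), c(1, 1, 5))
  expect_identical(resample_thickness(vol5, 5), vol5)
})

test_that("DICOM series reads to HU with normalized slice order", {
  stored <- array(1059L, c(8, 8, 3))
  stored[3, 5, 2] <- 1124L   # 100 HU landmark at (row 3, col 5, slice 2)
  d <- tempfile()
  write_dicom_series(d, stored, spacing = c(0.6, 0.8), thickness = 5)
  vol <- read_ct(d)
  # slope 1, intercept -1024: stored 1059 -> 35 HU
  expect_equal(vol$voxels[1, 1, 1], 35)
  expect_equal(vol$voxels[3, 5, 2], 100)
  expect_equal(vol$spacing, c(0.6, 0.8, 5))

  # shuffled file names must give the identical volume (sorted by position)
  d2 <- tempfile()
  write_dicom_series(d2, stored, spacing = c(0.6, 0.8), thickness = 5,
                     names = c("zzz.dcm", "aaa.dcm", "mmm.dcm"))
  expect_identical(read_ct(d2)$voxels, vol$voxels)

  # single-slice series is valid
  d3 <- tempfile()
  write_dicom_series(d3, stored[, , 1, drop = FALSE])
  expect_equal(dim(read_ct(d3)$voxels)[3], 1)
})

test_that("DICOM contract violations are rejected", {
  stored <- array(1000L, c(6, 6, 3))
  # duplicate slice position
  d <- tempfile(); dir.create(d)
  write_dicom_slice(file.path(d, "a.dcm"), stored[, , 1], position = c(0, 0, 0))
  write_dicom_slice(file.path(d, "b.dcm"), stored[, , 2], position = c(0, 0, 0),
                    uid_suffix = "2")
  expect_error(read_ct(d), "duplicate slice positions")
  # missing slice -> spacing gap beyond tolerance
  d <- tempfile(); dir.create(d)
  for (z in c(0, 5, 15))
    write_dicom_slice(file.path(d, sprintf("z%02d.dcm", z)), stored[, , 1],
                      position = c(0, 0, z), uid_suffix = as.character(z))
  expect_error(read_ct(d), "non-uniform slice spacing")
  # non-HU modality
  d <- tempfile()
  write_dicom_series(d, stored, modality = "MR")
  expect_error(read_ct(d), "non-HU modality")
})

test_that("the DICOM reader agrees with pydicom on a synthetic slice", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  f <- tempfile(fileext = ".dcm")
  set.seed(7)
  stored <- matrix(sample.int(2000L, 64, replace = TRUE), 8, 8)
  write_dicom_slice(f, stored, spacing = c(0.7, 0.9), intercept = -1024, slope = 1)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "a = ds.pixel_array.astype('float64') * float(ds.RescaleSlope) + float(ds.RescaleIntercept)",
    "print(float(a.sum()), ds.Rows, ds.Columns, float(a[2, 4]))"
  ), script)
  out <- system2(py, c(script, f), stdout = TRUE, stderr = FALSE)
  ref <- strsplit(trimws(out[length(out)]), " +")[[1]]
  slice <- asNamespace("hemovol")$read_dicom_file(f)
  hu <- slice$pixels * 1 + (-1024)
  expect_equal(sum(hu), as.numeric(ref[1]))
  expect_equal(hu[3, 5], as.numeric(ref[4]))
})
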