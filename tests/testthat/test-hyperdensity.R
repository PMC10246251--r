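test_that("brain median follows the midpoint convention", {
  vol <- ct_volume(array(35, c(4, 4, 2)), c(1, 1, 5))
  all_mask <- seg_mask(array(TRUE, c(4, 4, 2)), c(1, 1, 5))
  expect_equal(brain_median(vol, all_mask), 35)
  # half 30, half 40, even count -> midpoint 35
  vox <- array(rep(c(30, 40), each = 16), c(4, 4, 2))
  expect_equal(brain_median(ct_volume(vox, c(1, 1, 5)), all_mask), 35)
  # empty mask errors
  none <- seg_mask(array(FALSE, c(4, 4, 2)), c(1, 1, 5))
  expect_error(brain_median(vol, none), "empty")
})

test_that("noisy phantom brain median lands near the nominal 35 HU", {
  ph <- generate_phantom(small_phantom_spec(noise_sigma = 4, seed = 11L))
  m <- slice_range_filter(intracranial_mask(ph$volume))
  expect_lt(abs(brain_median(ph$volume, m) - 35), 1.0)
})

test_that("hyperdensity threshold is strictly greater than median + offset", {
  vox <- array(35, c(4, 4, 1))
  vox[1, 1, 1] <- 51   # just above 35 + 15
  vox[2, 1, 1] <- 50   # exactly at the threshold: excluded
  vol <- ct_volume(vox, c(1, 1, 5))
  all_mask <- seg_mask(array(TRUE, dim(vox)), vol$spacing)
  hy <- threshold_hyperdense(vol, all_mask, 35)
  expect_true(hy$voxels[1, 1, 1])
  expect_false(hy$voxels[2, 1, 1])
  expect_equal(sum(hy$voxels), 1)
  # unreachable offset -> empty mask
  hy2 <- threshold_hyperdense(vol, all_mask, 35, detection_params(hu_offset = 1e6))
  expect_equal(sum(hy2$voxels), 0)
})

test_that("detected voxel count is non-increasing in the HU offset", {
  ph <- generate_phantom(small_phantom_spec(
    noise_sigma = 4, seed = 3L,
    lesions = list(phantom_lesion(volume_cc = 20))))
  m <- slice_range_filter(intracranial_mask(ph$volume))
  med <- brain_median(ph$volume, m)
  counts <- vapply(c(10, 15, 20), function(off)
    sum(threshold_hyperdense(ph$volume, m, med,
                             detection_params(hu_offset = off))$voxels), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("component labelling matches connectivity definitions", {
  # two disjoint 10-voxel components
  m <- array(FALSE, c(10, 10, 4))
  m[1:5, 1, 1] <- TRUE; m[1:5, 1, 2] <- TRUE
  m[8:10, 9, 3] <- TRUE; m[8:10, 10, 3] <- TRUE; m[8:10, 9, 4] <- TRUE;
  m[10, 10, 4] <- TRUE
  lab <- label_components(seg_mask(m, c(1, 1, 1)))
  expect_equal(lab$n, 2)
  expect_equal(sort(tabulate(lab$labels[lab$labels > 0])), c(10, 10))

  # corner-touching voxels: one component at 26, two at 6
  m2 <- array(FALSE, c(3, 3, 3))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(label_components(seg_mask(m2, c(1, 1, 1)), 26)$n, 1)
  expect_equal(label_components(seg_mask(m2, c(1, 1, 1)), 6)$n, 2)
})

test_that("labelling agrees with a naive flood fill on random sparse masks", {
  set.seed(99)
  for (conn in c(6, 18, 26)) {
    m <- array(runif(7 * 6 * 5) < 0.25, c(7, 6, 5))
    lab <- label_components(seg_mask(m, c(1, 1, 1)), conn)
    oracle <- flood_fill_components(m, conn)
    expect_equal(lab$n, max(oracle))
    # same partition: labels must be a relabelling of the oracle
    expect_equal(length(unique(paste(lab$labels[m], oracle[m]))), lab$n)
  }
})

test_that("false-positive filter rejects small and dural components", {
  lab <- array(0L, c(10, 10, 4))
  lab[1:2, 1:2, 1] <- 1L                 # 4 voxels * 5 mm3 = 0.02 cc: floor
  lab[5:9, 5:9, 2:3] <- 2L               # 50 voxels = 1.25 cc in zone
  lab[1:9, 1:9, 4] <- 3L                 # 81 voxels = 2.03 cc, kept
  zone <- array(FALSE, c(10, 10, 4))
  zone[, , 2:3] <- TRUE
  comps <- structure(list(labels = lab, n = 3L, spacing = c(1, 5, 5),
                          connectivity = 26), class = "cc_labels")
  tab <- filter_false_positives(comps, seg_mask(zone, c(1, 5, 5)))
  expect_equal(tab$reason, c("below_detection_floor", "dural_structure", ""))
  expect_equal(tab$kept, c(FALSE, FALSE, TRUE))
  expect_equal(tab$volume_cc, c(4, 50, 81) * 25 / 1000)
})

test_that("volume computation is pixel area times slice thickness", {
  expect_equal(volume_cc(8000, spacing = c(0.5, 0.5, 5)), 10)
  expect_equal(volume_cc(seg_mask(array(FALSE, c(4, 4, 2)), c(1, 1, 5))), 0)
})

test_that("voxelized ellipsoid volume approximates the analytic volume", {
  ph <- generate_phantom(small_phantom_spec(
    lesions = list(phantom_lesion(semiaxes_mm = c(20, 16, 12)))))
  analytic <- 4 / 3 * pi * 20 * 16 * 12 / 1000
  voxel <- volume_cc(ph$truth$lesion_masks[[1]])
  # within half a voxel layer of the analytic ellipsoid volume
  half_layer <- pi * 20 * 16 / 1000 * small_phantom_spec()$spacing_mm[3] / 2
  expect_lt(abs(voxel - analytic), half_layer)
})

test_that("end-to-end detection keeps real lesions and sums their volumes", {
  ph <- generate_phantom(small_phantom_spec(
    noise_sigma = 4, seed = 21L,
    falx_plate = TRUE, sinus_blob = TRUE,
    lesions = list(phantom_lesion(center_mm = c(-20, 18, 0), volume_cc = 10),
                   phantom_lesion(center_mm = c(10, -35, 5), volume_cc = 3))))
  rep <- detect_ich(ph$volume)
  kept <- rep$components[rep$components$kept, ]
  expect_equal(nrow(kept), 2)
  expect_equal(rep$total_volume_cc, sum(kept$volume_cc))
  expect_equal(rep$threshold_hu, rep$brain_median_hu + 15)
  truth_total <- sum(ph$truth$lesion_voxel_cc)
  expect_lt(abs(rep$total_volume_cc - truth_total) / truth_total, 0.1)
})

test_that("merge-averaged thin-slice acquisition inflates volume only modestly", {
  # 2.5 mm acquisition merged to 5 mm: boundary voxels mixing lesion (70) and
  # brain (35) average to 52.5 HU, above threshold, so the measured volume
  # sits slightly above truth - bounded here at +10%
  ph <- generate_phantom(phantom_spec(
    noise_sigma = 4, seed = 5L,
    lesions = list(phantom_lesion(volume_cc = 25))))
  rep <- detect_ich(ph$volume)
  truth <- ph$truth$lesion_voxel_cc
  expect_gte(rep$total_volume_cc, truth * 0.98)
  expect_lte(rep$total_volume_cc, truth * 1.10)
})
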