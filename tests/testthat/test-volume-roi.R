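test_that("volume construction enforces magnitude-image invariants", {
  expect_error(mri_volume(array(1, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(mri_volume(array(1, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_warning(v <- mri_volume(array(c(-1, rep(2, 7)), c(2, 2, 2))),
                 "clamped")
  expect_equal(min(v$data), 0)
  m <- mri_mask(array(TRUE, c(2, 2, 2)), v)
  expect_identical(m$spacing, v$spacing)
  expect_error(mri_mask(array(TRUE, c(3, 2, 2)), v), "shape")
})

test_that("mask volume is voxel count times voxel volume, in mL", {
  v <- const_volume(dims = c(10, 10, 10), spacing = c(1, 1, 1))
  expect_equal(mask_volume_ml(full_mask(v)), 1)
  v2 <- const_volume(dims = c(1, 1, 1), spacing = c(1.37, 1.37, 4))
  expect_equal(mask_volume_ml(full_mask(v2)), 1.37 * 1.37 * 4 / 1000)
  empty <- mri_mask(array(FALSE, dim(v$data)), v)
  expect_equal(mask_volume_ml(empty), 0)
})

test_that("mask volume is additive over disjoint masks and monotone", {
  v <- const_volume(dims = c(8, 8, 8), spacing = c(1.5, 2, 2.5))
  set.seed(42)
  a <- array(runif(512) < 0.3, c(8, 8, 8))
  b <- array(runif(512) < 0.3, c(8, 8, 8)) & !a
  ma <- mri_mask(a, v); mb <- mri_mask(b, v)
  mu <- mri_mask(a | b, v)
  expect_equal(mask_volume_ml(mu), mask_volume_ml(ma) + mask_volume_ml(mb))
  expect_gte(mask_volume_ml(mu), mask_volume_ml(ma))
})

test_that("mean signal averages under the mask and rejects empty masks", {
  v <- const_volume(value = 7)
  expect_equal(mean_signal(v, full_mask(v)), 7)
  two <- array(FALSE, dim(v$data)); two[1:2] <- TRUE
  v$data[1:2] <- c(10, 30)
  expect_equal(mean_signal(v, mri_mask(two, v)), 20)
  expect_error(mean_signal(v, mri_mask(array(FALSE, dim(v$data)), v)),
               "empty")
})

test_that("ROI linear dimensions derive from the specified size", {
  expect_equal(roi_spec("sphere", c(0, 0, 0), size_cm3 = 2.03)$radius_mm,
               (3 * 2030 / (4 * pi))^(1 / 3), tolerance = 1e-12)
  expect_equal(2 * roi_spec("cube", c(0, 0, 0), size_cm3 = 2.03)$radius_mm,
               2030^(1 / 3), tolerance = 1e-12)
  expect_equal(roi_spec("disc", c(0, 0, 0), size_cm2 = 0.46,
                        slice_index = 1)$radius_mm,
               sqrt(46 / pi), tolerance = 1e-12)
  expect_error(roi_spec("disc", c(0, 0, 0), size_cm2 = 0.46), "slice_index")
  expect_error(roi_spec("sphere", c(0, 0, 0), size_cm3 = -1), "size_cm3")
})

test_that("sampling a constant volume returns the constant for every shape", {
  v <- const_volume(value = 3.5, dims = c(30, 30, 16), spacing = c(2, 2, 3))
  ctr <- v$origin + (dim(v$data) - 1) * v$spacing / 2
  for (roi in list(roi_spec("sphere", ctr, size_cm3 = 2.03),
                   roi_spec("cube", ctr, size_cm3 = 2.03),
                   roi_spec("disc", ctr, size_cm2 = 0.46, slice_index = 8)))
    expect_equal(sample_roi(v, roi), 3.5)
})

test_that("ROIs outside the grid or without voxel centres are rejected", {
  v <- const_volume(dims = c(10, 10, 10), spacing = c(2, 2, 2))
  expect_error(sample_roi(v, roi_spec("sphere", c(0, 0, 0), size_cm3 = 2.03)),
               "outside")
  coarse <- const_volume(dims = c(30, 30, 4), spacing = c(2, 2, 30))
  ctr <- coarse$origin + (dim(coarse$data) - 1) * coarse$spacing / 2
  ctr[3] <- ctr[3] + 15  # between slice centres
  expect_error(sample_roi(coarse, roi_spec("sphere", ctr, size_cm3 = 0.01)),
               "no voxel centres|outside")
})

test_that("normalization divides by the reference and is invertible", {
  expect_equal(normalize_signal(46, 200), 0.23)
  expect_equal(normalize_signal(200, 200), 1)
  expect_error(normalize_signal(5, 0), "positive")
  x <- runif(20, 1, 100); r <- 37.5
  expect_equal(normalize_signal(x, r) * r, x)
  # voxel-wise then average equals average then normalize
  v <- const_volume(value = 1)
  set.seed(7); v$data[] <- runif(length(v$data), 10, 50)
  m <- full_mask(v)
  expect_equal(mean_signal(normalize_signal(v, r), m),
               normalize_signal(mean_signal(v, m), r))
})

test_that("SNR is lung over air signal with a positive air floor", {
  expect_equal(snr(58, 1), 58)
  expect_equal(snr(12, 12), 1)
  expect_error(snr(10, 0), "positive")
})

test_that("ROI YAML configs round-trip", {
  rois <- list(
    muscle = roi_spec("disc", c(10, 80, 40), size_cm2 = 0.46,
                      slice_index = 12),
    atelectasis = roi_spec("cube", c(-40, 60, 30), size_cm3 = 2.03),
    water = roi_spec("sphere", c(0, 0, 0), size_cm3 = 2.03))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_roi_config(rois, f)
  back <- read_roi_config(f)
  expect_named(back, names(rois))
  for (nm in names(rois)) {
    expect_equal(back[[nm]]$shape, rois[[nm]]$shape)
    expect_equal(back[[nm]]$radius_mm, rois[[nm]]$radius_mm)
    expect_equal(back[[nm]]$center_mm, rois[[nm]]$center_mm)
  }
})
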