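norm_phantom <- function(noise_sigma = 0, seed = 1, ...) {
  ph <- generate_invivo_scan(invivo_config(noise_sigma = noise_sigma, ...),
                             seed = seed)
  refs <- mapply(function(b, r) sample_roi(b, r), ph$blocks, ph$muscle_rois)
  list(ph = ph, merged = merge_blocks(ph$blocks, refs))
}

test_that("voxel classification applies the half-open threshold bands", {
  v <- mri_volume(array(c(0.70, 0.40, 0.10, 0.5, 0.5, 0.5, 0.5, 0.5),
                        c(2, 2, 2)))
  m <- mri_mask(array(c(TRUE, TRUE, TRUE, rep(FALSE, 5)), c(2, 2, 2)), v)
  lab <- classify_voxels(v, m, threshold_set(0.64, 0.26))
  expect_equal(lab$labels[1:3], c(1L, 2L, 3L))  # non / poor / normal
  expect_equal(lab$labels[4:8], rep(0L, 5))     # outside the mask
  # exactly at a threshold: the upper class (inclusive lower bound)
  v$data[1:2] <- c(0.64, 0.26)
  lab2 <- classify_voxels(v, m, threshold_set(0.64, 0.26))
  expect_equal(lab2$labels[1:2], c(1L, 2L))
})

test_that("attenuation-scale thresholds are rejected for intensity volumes", {
  v <- const_volume(0.5)
  m <- full_mask(v)
  att <- threshold_set(0.70, 0.28, scale = "attenuation")
  expect_error(classify_voxels(v, m, att), "scale mismatch")
})

test_that("classification is invariant to a common intensity scale", {
  p <- norm_phantom()
  thr <- threshold_set(0.644, 0.2576)
  l1 <- classify_voxels(p$merged, p$ph$mask, thr)
  scaled <- p$merged; scaled$data <- scaled$data * 3.7
  l2 <- classify_voxels(scaled, p$ph$mask,
                        threshold_set(0.644 * 3.7, 0.2576 * 3.7))
  expect_identical(l1$labels, l2$labels)
})

test_that("compartment report conserves volume and percentages", {
  p <- norm_phantom()
  rep_ <- compartment_report(
    classify_voxels(p$merged, p$ph$mask, threshold_set(0.644, 0.2576)),
    p$ph$mask, volume_normalized = p$merged, scan_label = "pre")
  expect_equal(sum(rep_$volume_ml), rep_$total_lung_volume_ml,
               tolerance = 1e-9)
  expect_equal(sum(rep_$percent_of_tlv), 100, tolerance = 1e-6)
  expect_equal(rep_$total_lung_volume_ml, mask_volume_ml(p$ph$mask))
  row <- report_as_row(rep_)
  expect_equal(row$scan_label, "pre")
  expect_equal(row$nonaerated_pct, rep_$percent_of_tlv[["nonaerated"]])
  expect_output(print(rep_), "poorly aerated")
})

test_that("all voxels above the non-aerated threshold give 100% one class", {
  v <- const_volume(0.9, dims = c(10, 10, 5))
  m <- full_mask(v)
  rep_ <- compartment_report(classify_voxels(v, m, threshold_set(0.64, 0.26)),
                             m)
  expect_equal(unname(rep_$percent_of_tlv),  c(100, 0, 0))
})

test_that("painted compartment fractions are recovered end to end", {
  p <- norm_phantom()
  res <- run_invivo_quantification(p$ph$blocks, p$ph$mask, p$ph$muscle_rois,
                                   thresholds = threshold_set(0.644, 0.2576))
  err <- res$report$percent_of_tlv / 100 - p$ph$truth$class_fractions
  expect_lt(max(abs(err)) * 100, 1)  # within 1% of TLV, noiseless
  for (s in 1:6) {
    pn <- norm_phantom(noise_sigma = 0.05, seed = s)
    resn <- run_invivo_quantification(pn$ph$blocks, pn$ph$mask,
                                      pn$ph$muscle_rois,
                                      thresholds = threshold_set(0.644, 0.2576))
    errn <- resn$report$percent_of_tlv / 100 - pn$ph$truth$class_fractions
    expect_lt(max(abs(errn)) * 100, 3)  # within 3% of TLV under Rician noise
  }
})

test_that("the ventro-dorsal split partitions the mask at equal extent", {
  p <- norm_phantom()
  halves <- ventro_dorsal_split(p$ph$mask)
  expect_false(any(halves$ventral$data & halves$dorsal$data))
  expect_identical(halves$ventral$data | halves$dorsal$data, p$ph$mask$data)
  # symmetric ellipsoids: halves within one slice-plane of voxels
  ap_plane <- prod(dim(p$ph$mask$data)[c(1, 3)])
  expect_lt(abs(sum(halves$ventral$data) - sum(halves$dorsal$data)), ap_plane)
  # dorsal signal exceeds ventral when the gradient is painted
  expect_gt(mean_signal(p$merged, halves$dorsal),
            mean_signal(p$merged, halves$ventral))
})

test_that("atelectasis reference reads the painted value and flags mixtures", {
  p <- norm_phantom()
  expect_equal(atelectasis_reference(p$merged, p$ph$atel_roi, p$ph$mask),
               0.92, tolerance = 1e-9)
  v <- const_volume(1.0, dims = c(30, 30, 12), spacing = c(2, 2, 2))
  ctr <- v$origin + (dim(v$data) - 1) * v$spacing / 2
  expect_equal(atelectasis_reference(v, roi_spec("cube", ctr,
                                                 size_cm3 = 2.03)), 1.0)
  # half the cube at aerated intensity: mean drops below the painted value
  mixed <- v; mixed$data[1:15, , ] <- 0.2
  expect_warning(val <- atelectasis_reference(
    mixed, roi_spec("cube", ctr, size_cm3 = 2.03)), "heterogeneous")
  expect_lt(val, 1.0)
  # ROI outside the lung mask errors
  m <- mri_mask(array(FALSE, dim(v$data)), v)
  expect_error(atelectasis_reference(v, roi_spec("cube", ctr,
                                                 size_cm3 = 2.03), m),
               "outside the lung mask")
})

test_that("threshold sensitivity is zero off-histogram and monotone", {
  p <- norm_phantom()  # painted bands keep clear of the thresholds
  sens <- threshold_sensitivity(p$merged, p$ph$mask,
                                threshold_set(0.644, 0.2576))
  expect_equal(attr(sens, "max_abs_delta"), 0)
  # raising the non-aerated threshold never increases the non-aerated class
  thr <- threshold_set(0.50, 0.2576)  # sits inside the poor band on purpose
  sens2 <- threshold_sensitivity(p$merged, p$ph$mask, thr)
  up <- sens2[sens2$scenario == "nonaerated_up", ]
  expect_lte(up$delta_nonaerated_pct, 0)
  down <- sens2[sens2$scenario == "nonaerated_down", ]
  expect_gte(down$delta_nonaerated_pct, 0)
})

test_that("pre/post phantom pair shows the post-operative aeration loss", {
  pre <- norm_phantom(atelectasis = FALSE, frac_poor = 0.08)
  post <- norm_phantom(lung_semi_mm = c(27, 36, 58))  # smaller lungs + atelectasis
  thr <- threshold_set(0.644, 0.2576)
  r_pre <- run_invivo_quantification(pre$ph$blocks, pre$ph$mask,
                                     pre$ph$muscle_rois, thresholds = thr)$report
  r_post <- run_invivo_quantification(post$ph$blocks, post$ph$mask,
                                      post$ph$muscle_rois, thresholds = thr)$report
  expect_lt(r_post$total_lung_volume_ml, r_pre$total_lung_volume_ml)
  expect_gt(r_post$percent_of_tlv[["nonaerated"]],
            r_pre$percent_of_tlv[["nonaerated"]])
  expect_gt(r_post$percent_of_tlv[["poorly_aerated"]],
            r_pre$percent_of_tlv[["poorly_aerated"]])
})
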