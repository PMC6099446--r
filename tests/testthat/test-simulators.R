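test_that("ex vivo truth table is internally consistent", {
  sim <- simulate_exvivo_samples(exvivo_config(), seed = 8)
  tr <- sim$truth$table
  mass <- sim$truth$mass_g[tr$sample_id]
  expect_equal(tr$density_g_ml * tr$volume_ml, unname(mass), tolerance = 1e-9)
  # recomputing the gas fraction from truth volumes matches the stored one
  v0 <- tr$volume_ml[tr$cpap_cmh2o == 0][match(tr$sample_id,
        tr$sample_id[tr$cpap_cmh2o == 0])]
  expect_equal((tr$volume_ml - v0) / tr$volume_ml, tr$gas_fraction,
               tolerance = 1e-12)
  expect_equal(tr$attenuation[tr$cpap_cmh2o == 0],
               rep(1, sum(tr$cpap_cmh2o == 0)))
})

test_that("generation is reproducible under a fixed seed", {
  a <- simulate_exvivo_samples(exvivo_config(), seed = 99)
  b <- simulate_exvivo_samples(exvivo_config(), seed = 99)
  expect_identical(a$samples, b$samples)
  c1 <- generate_invivo_scan(invivo_config(noise_sigma = 0.05), seed = 12)
  c2 <- generate_invivo_scan(invivo_config(noise_sigma = 0.05), seed = 12)
  expect_identical(c1$blocks[[1]]$data, c2$blocks[[1]]$data)
})

test_that("config invariants are enforced", {
  expect_error(exvivo_config(inflation_factors = c("0" = 1.2, "40" = 3)),
               "must be 1")
  expect_error(exvivo_config(inflation_factors = c("0" = 1, "40" = 2,
                                                   "10" = 3, "2" = 1.5)),
               "non-decreasing")
  expect_error(invivo_config(n_blocks = 4), "2 or 3")
  expect_error(invivo_config(frac_nonaerated = 0.7, frac_poor = 0.5),
               "sum to at most 1")
})

test_that("Rician noise has the expected magnitude-image behaviour", {
  v <- const_volume(value = 40, dims = c(30, 30, 10))
  expect_identical(add_rician_noise(v, 0), v)
  expect_error(add_rician_noise(v, -1), "non-negative")
  # Rayleigh mean in signal-free voxels: sigma * sqrt(pi/2)
  zeros <- array(0, c(50, 50, 40))  # 1e5 draws
  noisy <- add_rician_noise(zeros, 3, seed = 5)
  expect_equal(mean(noisy), 3 * sqrt(pi / 2), tolerance = 0.01)
  # determinism
  expect_identical(add_rician_noise(v, 2, seed = 7),
                   add_rician_noise(v, 2, seed = 7))
})

test_that("voxelized scans reproduce the analytic truth through the pipeline", {
  dset <- generate_exvivo_dataset(tiny_imaging_config(), seed = 2)
  key <- merge(dset$samples, dset$truth$table,
               by = c("sample_id", "cpap_cmh2o"))
  # volumetry: rasterization error of an ellipsoid stays below 2% relative
  expect_lt(max(abs(key$volume_ml.x - key$volume_ml.y) / key$volume_ml.y),
            0.02)
  # painted signal measured exactly at sigma = 0 (constant under the mask)
  gains <- dset$truth$table$session_gain[
    match(key$sample_id, dset$truth$table$sample_id)]
  expect_equal(key$mean_signal_gu,
               key$signal_normalized * 800 * gains, tolerance = 1e-9)
  # reference ROIs return the painted tube values
  expect_equal(key$water_ref_gu, 1000 * gains, tolerance = 1e-9)
  expect_equal(key$muscle_ref_gu, 800 * gains, tolerance = 1e-9)
  # calibration through images recovers the generating quadratic closely
  fit <- expect_silent_fit(fit_density_signal(dset$samples, "quadratic",
                                              "muscle"))
  expect_lt(abs(fit$a - 1.22), 0.01)
  expect_lt(abs(fit$b - 0.05), 0.005)
})

test_that("SNR decreases with inflation at fixed noise", {
  cfg <- tiny_imaging_config(n_healthy = 1L, n_injured = 0L,
                             noise_sigma_gu = 3)
  # needs >= 3 samples only for fitting; generation works with one
  dset <- generate_exvivo_dataset(cfg, seed = 4)
  s <- dset$samples
  s <- s[order(match(s$cpap_cmh2o, c(0, 2, 10, 40))), ]
  snrs <- mapply(snr, s$mean_signal_gu, s$air_ref_gu)
  expect_true(all(diff(snrs) < 0))
  # air ROI mean sits near the Rayleigh-lifted floor, not at zero
  expect_gt(min(s$air_ref_gu), 1)
})

test_that("the thorax phantom paints exact compartment fractions", {
  ph <- generate_invivo_scan(invivo_config(), seed = 1)
  expect_equal(unname(ph$truth$class_fractions[1]), 0.10, tolerance = 1e-3)
  expect_equal(unname(ph$truth$class_fractions[2]), 0.16, tolerance = 1e-3)
  expect_equal(sum(ph$truth$class_counts), sum(ph$mask$data))
  expect_gt(ph$truth$dorsal_mean, ph$truth$ventral_mean)
  # atelectasis off: no non-aerated voxels
  ph0 <- generate_invivo_scan(invivo_config(atelectasis = FALSE), seed = 1)
  expect_equal(unname(ph0$truth$class_counts[1]), 0L)
  expect_null(ph0$atel_roi)
})

test_that("per-block gain cancels after muscle normalization", {
  ph <- generate_invivo_scan(invivo_config(), seed = 3)
  refs <- mapply(function(b, r) sample_roi(b, r), ph$blocks, ph$muscle_rois)
  merged <- merge_blocks(ph$blocks, refs)
  # the merged normalized volume equals the painted field where tissue
  # is present, independent of the per-block gains
  tissue <- ph$truth$normalized_volume$data > 0
  expect_equal(merged$data[tissue], ph$truth$normalized_volume$data[tissue],
               tolerance = 1e-9)
})

test_that("an oversized atelectasis or undersized lung is rejected", {
  expect_error(
    generate_invivo_scan(invivo_config(frac_nonaerated = 0.6,
                                       frac_poor = 0.1), seed = 1),
    "does not fit")
  expect_error(
    generate_invivo_scan(invivo_config(lung_semi_mm = c(4, 4, 4)), seed = 1),
    "too small")
})
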