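test_that("noiseless quadratic data are recovered to numerical precision", {
  sim <- simulate_exvivo_samples(noiseless_exvivo_config(), seed = 3)
  fit <- expect_silent_fit(fit_density_signal(sim$samples, "quadratic",
                                              "muscle"))
  expect_equal(fit$a, 1.22, tolerance = 1e-6)
  expect_equal(fit$b, 0.05, tolerance = 1e-6)
  expect_lt(fit$sigma_sample, 1e-8)  # no between-sample variance generated
  # water normalization rescales the signal axis; the quadratic
  # coefficient absorbs the square of the scale
  fw <- expect_silent_fit(fit_density_signal(sim$samples, "quadratic",
                                             "water"))
  expect_equal(fw$a, 1.22 * (1000 / 800)^2, tolerance = 1e-6)
  expect_equal(fw$b, 0.05, tolerance = 1e-6)
})

test_that("AICc prefers the generating model form", {
  sim <- simulate_exvivo_samples(exvivo_config(), seed = 17)
  fq <- expect_silent_fit(fit_density_signal(sim$samples, "quadratic", "muscle"))
  fl <- expect_silent_fit(fit_density_signal(sim$samples, "linear", "muscle"))
  expect_lt(fq$aicc, fl$aicc)
  tab <- expect_silent_fit(density_model_table(sim$samples))
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$model_form[tab$best], "quadratic")
})

test_that("an injury offset in the generator is detected by the LRT", {
  sim <- simulate_exvivo_samples(exvivo_config(injury_density_offset = 0.1),
                                 seed = 23)
  fit <- expect_silent_fit(fit_density_signal(sim$samples, "quadratic",
                                              "muscle"))
  expect_lt(fit$evlw_effect_p, 0.05)
  expect_lt(abs(fit$injury_effect - 0.1), 0.03)
  # and is not spuriously detected at offset 0 (a single seeded check)
  sim0 <- simulate_exvivo_samples(exvivo_config(), seed = 23)
  fit0 <- expect_silent_fit(fit_density_signal(sim0$samples, "quadratic",
                                               "muscle"))
  expect_gt(fit0$evlw_effect_p, 0.05)
})

test_that("density fit methods are coherent", {
  sim <- simulate_exvivo_samples(exvivo_config(), seed = 2)
  fit <- expect_silent_fit(fit_density_signal(sim$samples, "quadratic",
                                              "muscle"))
  expect_named(coef(fit), c("a", "b", "injury"))
  expect_equal(predict(fit, 0.5),
               fit$b + fit$a * 0.25)
  expect_output(print(fit), "Density-signal calibration")
  expect_output(print(summary(fit)), "AICc")
  few <- sim$samples[sim$samples$sample_id %in% c("S01", "S02"), ]
  expect_error(fit_density_signal(few), "at least 3 samples")
})

test_that("proportional signal yields the analytic attenuation limit", {
  cfg <- noiseless_exvivo_config(signal_model = "proportional")
  sim <- simulate_exvivo_samples(cfg, seed = 1)
  fit <- expect_silent_fit(fit_attenuation_line(sim$samples, "muscle"))
  expect_equal(fit$slope, -1, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  thr <- derive_thresholds(fit, reps = 200, seed = 1)
  expect_equal(thr$t_nonaerated, 0.9, tolerance = 1e-9)
  expect_equal(thr$t_poor, 0.5, tolerance = 1e-9)
})

test_that("attenuation fit rejects degenerate gas-fraction ranges", {
  tab <- data.frame(sample_id = rep(sprintf("S%02d", 1:4), each = 2),
                    gas_fraction = 0.4, attenuation = runif(8),
                    reference = FALSE)
  expect_error(expect_silent_fit(fit_attenuation_line(tab)), "degenerate")
})

test_that("study-matched synthetic attenuation data give R^2 near 0.93", {
  r2 <- vapply(1:50, function(s)
    expect_silent_fit(fit_attenuation_line(study_attenuation_data(s)))$r_squared,
    0)
  expect_equal(mean(r2), 0.93, tolerance = 0.05)
  expect_true(all(r2 > 0.85 & r2 < 1))
})

test_that("thresholds follow the line and CIs contain the point estimate", {
  tab <- simulate_attenuation_data(seed = 4)
  fit <- expect_silent_fit(fit_attenuation_line(tab))
  thr <- derive_thresholds(fit, reps = 500, seed = 9)
  expect_equal(thr$t_nonaerated, fit$intercept + fit$slope * 0.1)
  expect_equal(thr$t_poor, fit$intercept + fit$slope * 0.5)
  expect_gt(thr$t_nonaerated, thr$t_poor)  # negative slope ordering
  expect_true(thr$ci_nonaerated[1] <= thr$t_nonaerated &&
              thr$t_nonaerated <= thr$ci_nonaerated[2])
  expect_true(thr$ci_poor[1] <= thr$t_poor && thr$t_poor <= thr$ci_poor[2])
  expect_error(derive_thresholds(fit, cutoffs = c(0.1, 1)), "\\[0, 1\\)")
})

test_that("same seed gives identical bootstrap intervals", {
  tab <- simulate_attenuation_data(seed = 6)
  fit <- expect_silent_fit(fit_attenuation_line(tab))
  t1 <- derive_thresholds(fit, reps = 200, seed = 42)
  t2 <- derive_thresholds(fit, reps = 200, seed = 42)
  expect_identical(t1$ci_nonaerated, t2$ci_nonaerated)
  expect_identical(t1$ci_poor, t2$ci_poor)
})

test_that("threshold translation multiplies by the atelectasis reference", {
  thr <- translate_thresholds(0.92, c(0.70, 0.28))
  expect_equal(thr$t_nonaerated, 0.644)
  expect_equal(thr$t_poor, 0.2576)
  expect_equal(thr$rounded, c(0.64, 0.26))
  ident <- translate_thresholds(1, c(0.70, 0.28))
  expect_equal(ident$t_nonaerated, 0.70)
  expect_equal(ident$t_poor, 0.28)
  expect_error(translate_thresholds(0, c(0.7, 0.28)), "positive")
  expect_error(translate_thresholds(0.92, c(0.28, 0.70)), "non-aerated > poor")
  expect_equal(thr$scale, "muscle_normalized")
})
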