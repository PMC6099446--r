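test_that("density is mass over volume in g/mL", {
  expect_equal(compute_density(100, 100), 1)
  expect_equal(compute_density(93.6, 120), 0.78)
  expect_equal(compute_density(150, 300), 0.5)
  expect_error(compute_density(100, 0), "positive")
})

test_that("gas fraction is (V - V0)/V with clamping below -0.05", {
  expect_equal(compute_gas_fraction(100, 100), 0)
  expect_equal(compute_gas_fraction(200, 100), 0.5)
  expect_equal(compute_gas_fraction(1000 / 9, 100), 0.1)  # solve (V-100)/V = 0.1
  expect_warning(gf <- compute_gas_fraction(80, 100), "clamped")
  expect_equal(gf, -0.05)
  expect_error(compute_gas_fraction(0, 100), "positive")
})

test_that("attenuation is the signal ratio to the deflated scan", {
  expect_equal(compute_attenuation(55, 55), 1)
  expect_equal(compute_attenuation(27.5, 55), 0.5)
  expect_error(compute_attenuation(10, 0), "positive")
  # invariant to a shared normalization scalar
  s <- c(80, 60, 40); ref <- 173
  expect_equal(compute_attenuation(s / ref, s[1] / ref),
               compute_attenuation(s, s[1]))
})

test_that("attenuation table pins every deflated row at (0, 1)", {
  sim <- simulate_exvivo_samples(exvivo_config(), seed = 11)
  tab <- attenuation_table(sim$samples, "muscle")
  ref <- tab[tab$reference, ]
  expect_equal(ref$gas_fraction, rep(0, nrow(ref)))
  expect_equal(ref$attenuation, rep(1, nrow(ref)))
  expect_equal(sort(unique(tab$cpap_cmh2o)), c(0, 2, 10, 40))
})

test_that("descriptives reproduce the tabulated sample characteristics", {
  desc <- descriptive_stats(lung_sample_characteristics())
  expect_equal(round(desc$mass_mean_g, 1), 131.4)
  expect_equal(round(desc$mass_sd_g, 1), 34.6)  # population SD (divisor n)
  expect_equal(round(desc$evlw_mean, 2), 0.33)
  expect_equal(round(desc$evlw_sd, 2), 0.02)
  expect_equal(desc$n_samples, 11L)
  expect_equal(desc$n_injured, 3L)
  # sample SD (divisor n-1) would NOT reproduce the tabulated 34.6
  expect_equal(round(sd(lung_sample_characteristics()$mass_g), 1), 36.3)
})

test_that("correlation sample size follows the two-sided Fisher-z formula", {
  expect_equal(sample_size_for_correlation(0.8, 0.05, 0.90), 12L)
  expect_equal(sample_size_for_correlation(0.99, 0.05, 0.90), 5L)
  expect_lt(sample_size_for_correlation(0.8, 0.05, 0.50),
            sample_size_for_correlation(0.8, 0.05, 0.90))
  expect_error(sample_size_for_correlation(1), "0 < |r| < 1", fixed = TRUE)
})

test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(0, 2, 44), 4 + 12 / 41)
  expect_equal(aicc(-10, 0, 5), 20)
  # large-n limit is plain AIC
  expect_equal(aicc(-3, 4, 1e9), -2 * (-3) + 8, tolerance = 1e-6)
  expect_error(aicc(0, 5, 6), "n_obs")
})

test_that("sample tables validate and round-trip through CSV", {
  sim <- simulate_exvivo_samples(exvivo_config(), seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sample_table(sim$samples, f)
  back <- read_sample_table(f)
  expect_equal(back$mean_signal_gu, sim$samples$mean_signal_gu)
  bad <- sim$samples; bad$mass_g <- NULL
  expect_error(validate_sample_table(bad), "mass_g")
  no_ref <- sim$samples[sim$samples$cpap_cmh2o != 0, ]
  expect_error(validate_sample_table(no_ref), "0 cmH2O")
})
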