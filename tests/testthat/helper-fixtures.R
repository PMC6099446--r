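# Shared fixtures: everything is generated in code at test time.

const_volume <- function(value = 7, dims = c(24, 24, 12),
                         spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  mri_volume(array(value, dims), spacing = spacing, origin = origin)
}

full_mask <- function(volume) {
  mri_mask(array(TRUE, dim(volume$data)), volume)
}

# noiseless table-level ex vivo configuration (closed-loop recovery)
noiseless_exvivo_config <- function(...) {
  exvivo_config(signal_noise_sd = 0, volume_noise_frac = 0,
                ref_noise_frac = 0, sample_offset_sd = 0, ...)
}

# small-geometry configuration for image-level tests (coarse grid, light lungs)
tiny_imaging_config <- function(n_healthy = 2L, n_injured = 1L, ...) {
  exvivo_config(n_healthy = n_healthy, n_injured = n_injured,
                mass_mean_g = 25, mass_sd_g = 4, mass_min_g = 15,
                spacing = c(3, 3, 4), signal_noise_sd = 0,
                volume_noise_frac = 0, ref_noise_frac = 0,
                sample_offset_sd = 0, ...)
}

# frozen study-matched attenuation data: pinned deflated reference,
# between-lung sd 0.02, residual sd 0.042 (calibrated once to give the
# fit statistic R^2 ~ 0.93)
study_attenuation_data <- function(seed) {
  simulate_attenuation_data(sample_sd = 0.02, resid_sd = 0.042,
                            pin_reference = TRUE, seed = seed)
}

expect_silent_fit <- function(expr) suppressWarnings(expr)
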