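#' Configuration for the ex vivo lung-sample simulator
#'
#' Describes a bench study of isolated lung samples scanned at airway
#' pressures 0, 40, 10 and 2 cmH2O together with water and muscle
#' reference tubes: sample masses, inflation per pressure, the
#' density-signal law used to paint intensities, reference tube signals,
#' session gains and noise levels. Defaults mirror the study design the
#' package targets: 8 healthy + 3 injured samples with mass 131.4 ± 34.6 g.
#'
#' The signal model paints the normalized lung signal as the exact inverse
#' of the analysis-direction quadratic \code{density = a*s^2 + b}
#' (\code{"quadratic"}), so calibration fitting is a closed loop; the
#' \code{"proportional"} mode (signal proportional to density) provides
#' the analytic limit in which attenuation equals \code{1 - GAS_F}, i.e.
#' slope -1 and intercept 1.
#'
#' @param n_healthy,n_injured sample counts per group.
#' @param mass_mean_g,mass_sd_g,mass_min_g sample mass distribution (g).
#' @param evlw_mean,evlw_sd retained fluid per gram for injured samples.
#' @param specific_volume_ml_per_g deflated lung volume per gram (mL/g).
#' @param inflation_factors named vector, volume multiplier per CPAP level
#'   (cmH2O); must include \code{"0"} with value 1, non-decreasing with
#'   pressure.
#' @param signal_model \code{"quadratic"} or \code{"proportional"}.
#' @param quad_a,quad_b coefficients of \code{density = a*s^2 + b} on the
#'   muscle-normalized signal scale.
#' @param prop_coef proportionality constant for the proportional mode
#'   (normalized signal per g/mL).
#' @param injury_density_offset additive density offset (g/mL) of injured
#'   samples in the density-signal relation (0 = no covariate effect).
#' @param sample_offset_sd per-sample random intercept SD (g/mL) in the
#'   density-signal relation.
#' @param signal_noise_sd measurement noise SD on the normalized signal.
#' @param volume_noise_frac multiplicative noise SD on measured volumes.
#' @param ref_noise_frac multiplicative noise SD on reference signals.
#' @param water_gu,muscle_gu,air_floor_gu reference intensities (GU).
#' @param session_gains per-session scanner gain; samples are assigned to
#'   sessions round-robin.
#' @param spacing voxel spacing (mm) for image generation.
#' @param noise_sigma_gu Rician noise SD (GU) for image generation.
#' @return A validated list of class \code{exvivo_config}.
#' @export
exvivo_config <- function(n_healthy = 8L, n_injured = 3L,
                          mass_mean_g = 131.4, mass_sd_g = 34.6,
                          mass_min_g = 50,
                          evlw_mean = 0.33, evlw_sd = 0.02,
                          specific_volume_ml_per_g = 0.96,
                          inflation_factors = c("0" = 1, "40" = 3.57,
                                                "10" = 2.22, "2" = 1.54),
                          signal_model = c("quadratic", "proportional"),
                          quad_a = 1.22, quad_b = 0.05,
                          prop_coef = 0.88,
                          injury_density_offset = 0,
                          sample_offset_sd = 0.02,
                          signal_noise_sd = 0.015,
                          volume_noise_frac = 0.01,
                          ref_noise_frac = 0.005,
                          water_gu = 1000, muscle_gu = 800,
                          air_floor_gu = 2,
                          session_gains = c(1, 1.15, 0.9),
                          spacing = c(1.37, 1.37, 4),
                          noise_sigma_gu = 0) {
  signal_model <- match.arg(signal_model)
  if (n_healthy + n_injured < 1L) stop("need at least one sample")
  if (is.null(names(inflation_factors)) || !"0" %in% names(inflation_factors))
    stop("'inflation_factors' must be named by CPAP level and include \"0\"")
  if (abs(inflation_factors[["0"]] - 1) > 1e-12)
    stop("inflation factor at 0 cmH2O must be 1")
  ord <- as.numeric(names(inflation_factors))
  if (any(inflation_factors[order(ord)] != sort(inflation_factors)))
    stop("inflation factors must be non-decreasing with CPAP level")
  if (any(inflation_factors < 1)) stop("inflation factors must be >= 1")
  if (any(c(water_gu, muscle_gu, mass_mean_g, mass_sd_g) <= 0) ||
      air_floor_gu < 0)
    stop("GU references and mass parameters must be positive")
  structure(as.list(environment()), class = "exvivo_config")
}

## normalized lung signal implied by the configured density-signal law
lung_signal_from_density <- function(cfg, density, injured, u, sample_id) {
  if (cfg$signal_model == "quadratic") {
    arg <- (density - cfg$quad_b - cfg$injury_density_offset * injured - u) /
      cfg$quad_a
    if (any(arg <= 0))
      stop("density outside the invertible range of the signal model for sample(s): ",
           paste(unique(sample_id[arg <= 0]), collapse = ", "))
    sqrt(arg)
  } else {
    cfg$prop_coef * (density + cfg$injury_density_offset * injured + u)
  }
}

#' Simulate an ex vivo sample table with known truth
#'
#' Table-level simulation of the full bench protocol (no images): draws
#' sample masses and the injury group, computes per-pressure volumes from
#' the inflation factors, paints the mean lung signal through the inverse
#' of the configured density-signal law, applies session gains, reference
#' jitter and measurement noise, and returns both the observable sample
#' table and the noiseless ground truth.
#'
#' @param config an [exvivo_config()].
#' @param seed RNG seed; generation is reproducible bit-for-bit.
#' @return list with \code{samples} (the measurable table, see
#'   [validate_sample_table()]) and \code{truth} (per-row true volumes,
#'   densities, gas fractions, attenuations and normalized signals, plus
#'   the generating parameters and seed).
#' @export
simulate_exvivo_samples <- function(config = exvivo_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  n <- cfg$n_healthy + cfg$n_injured
  group <- c(rep("healthy", cfg$n_healthy), rep("injured", cfg$n_injured))
  mass <- pmax(cfg$mass_min_g, stats::rnorm(n, cfg$mass_mean_g, cfg$mass_sd_g))
  evlw <- ifelse(group == "injured",
                 pmax(0, stats::rnorm(n, cfg$evlw_mean, cfg$evlw_sd)), NA_real_)
  u <- stats::rnorm(n, 0, cfg$sample_offset_sd)
  gains <- cfg$session_gains[(seq_len(n) - 1L) %% length(cfg$session_gains) + 1L]
  pressures <- as.numeric(names(cfg$inflation_factors))

  rows <- list(); truth_rows <- list()
  for (i in seq_len(n)) {
    v0 <- mass[i] * cfg$specific_volume_ml_per_g
    for (p in pressures) {
      f <- cfg$inflation_factors[[as.character(p)]]
      v_true <- v0 * f
      d_true <- mass[i] / v_true
      s_true <- lung_signal_from_density(cfg, d_true, group[i] == "injured",
                                         u[i], sprintf("S%02d", i))
      s_obs <- s_true + stats::rnorm(1L, 0, cfg$signal_noise_sd)
      v_obs <- v_true * (1 + stats::rnorm(1L, 0, cfg$volume_noise_frac))
      jit <- function() 1 + stats::rnorm(1L, 0, cfg$ref_noise_frac)
      muscle_ref <- cfg$muscle_gu * gains[i] * jit()
      water_ref <- cfg$water_gu * gains[i] * jit()
      air_ref <- max(cfg$air_floor_gu * jit(), 1e-6)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("S%02d", i), group = group[i],
        cpap_cmh2o = p, mass_g = mass[i], volume_ml = v_obs,
        mean_signal_gu = s_obs * cfg$muscle_gu * gains[i],
        water_ref_gu = water_ref, muscle_ref_gu = muscle_ref,
        air_ref_gu = air_ref, evlw_g_per_g = evlw[i])
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sample_id = sprintf("S%02d", i), cpap_cmh2o = p,
        volume_ml = v_true, density_g_ml = d_true,
        gas_fraction = (v_true - v0) / v_true,
        attenuation = s_true /
          lung_signal_from_density(cfg, mass[i] / v0, group[i] == "injured",
                                   u[i], sprintf("S%02d", i)),
        signal_normalized = s_true, sample_offset = u[i],
        session_gain = gains[i])
    }
  }
  samples <- do.call(rbind, rows)
  validate_sample_table(samples)
  list(samples = samples,
       truth = list(table = do.call(rbind, truth_rows),
                    mass_g = stats::setNames(mass, sprintf("S%02d", seq_len(n))),
                    params = cfg, seed = seed))
}

#' Simulate attenuation-gas fraction observations from a known line
#'
#' Direct statistical simulation of the attenuation regression: 11 lungs
#' (by default) with one observation per pressure level, each drawn from
#' \code{attenuation = intercept + slope*gas_fraction + u_lung + noise}.
#' Used to study estimator properties (bias, bootstrap CI coverage) under
#' a known truth; by default all four levels (including gas fraction 0)
#' are drawn from the line with a single residual noise and no between-
#' lung term, so the fitted regression is exactly the generating model.
#' \code{pin_reference = TRUE} instead emulates the physical ratio
#' pipeline, whose deflated scan sits at (0, 1) by construction and is
#' flagged \code{reference}.
#'
#' @param n_samples number of lungs.
#' @param slope,intercept true line.
#' @param gasf_levels mean gas fraction per pressure level, named by CPAP
#'   (cmH2O).
#' @param gasf_jitter_sd between-lung SD of the achieved gas fraction
#'   (levels at exactly 0 are not jittered).
#' @param sample_sd SD of an optional per-lung random intercept.
#' @param resid_sd residual SD of attenuation observations.
#' @param pin_reference emit the 0 cmH2O row as the pipeline's pinned
#'   (0, 1) reference instead of drawing it from the line.
#' @param seed RNG seed.
#' @return data.frame with columns \code{sample_id}, \code{cpap_cmh2o},
#'   \code{gas_fraction}, \code{attenuation}, \code{reference}; attributes
#'   \code{slope}, \code{intercept} carry the truth.
#' @export
simulate_attenuation_data <- function(n_samples = 11L, slope = -1.05,
                                      intercept = 0.805,
                                      gasf_levels = c("0" = 0, "2" = 0.35,
                                                      "10" = 0.55,
                                                      "40" = 0.72),
                                      gasf_jitter_sd = 0.04,
                                      sample_sd = 0, resid_sd = 0.03,
                                      pin_reference = FALSE,
                                      seed = 1L) {
  set.seed(seed)
  u <- stats::rnorm(n_samples, 0, sample_sd)
  rows <- list()
  for (i in seq_len(n_samples)) {
    sid <- sprintf("S%02d", i)
    for (p in names(gasf_levels)) {
      lv <- gasf_levels[[p]]
      if (lv == 0 && pin_reference) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, cpap_cmh2o = as.numeric(p), gas_fraction = 0,
          attenuation = 1, reference = TRUE)
        next
      }
      g <- if (lv == 0) 0 else
        min(0.95, max(0.02, lv + stats::rnorm(1L, 0, gasf_jitter_sd)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, cpap_cmh2o = as.numeric(p), gas_fraction = g,
        attenuation = intercept + slope * g + u[i] +
          stats::rnorm(1L, 0, resid_sd),
        reference = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "slope") <- slope
  attr(out, "intercept") <- intercept
  out
}

#' Add Rician noise to a magnitude image
#'
#' Magnitude MRI noise: each voxel value v becomes
#' \code{sqrt((v + n1)^2 + n2^2)} with n1, n2 independent zero-mean
#' Gaussians of SD \code{sigma}. In signal-free (air) regions this reduces
#' to Rayleigh noise with mean \code{sigma * sqrt(pi/2)}, which is why the
#' background of a magnitude image never averages to zero.
#'
#' @param volume an \code{mri_volume} or numeric array.
#' @param sigma noise SD (GU), >= 0; 0 is the identity.
#' @param seed optional seed for reproducibility.
#' @return Same type as \code{volume}.
#' @export
add_rician_noise <- function(volume, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("'sigma' must be a single non-negative value")
  if (sigma == 0) return(volume)
  if (!is.null(seed)) set.seed(seed)
  v <- if (inherits(volume, "mri_volume")) volume$data else volume
  n <- length(v)
  noisy <- sqrt((v + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (inherits(volume, "mri_volume")) {
    volume$data <- array(noisy, dim(v))
    volume
  } else {
    array(noisy, dim(v))
  }
}

## rasterize an axis-aligned ellipsoid as a logical array on a grid
rasterize_ellipsoid <- function(dims, spacing, origin, center, semi) {
  cx <- origin[1L] + (seq_len(dims[1L]) - 1) * spacing[1L]
  cy <- origin[2L] + (seq_len(dims[2L]) - 1) * spacing[2L]
  cz <- origin[3L] + (seq_len(dims[3L]) - 1) * spacing[3L]
  qx <- ((cx - center[1L]) / semi[1L])^2
  qy <- ((cy - center[2L]) / semi[2L])^2
  qz <- ((cz - center[3L]) / semi[3L])^2
  outer(outer(qx, qy, `+`), qz, `+`) <= 1
}

#' Generate voxelized ex vivo scans with reference tubes
#'
#' Image-level counterpart of [simulate_exvivo_samples()]: for each sample
#' and pressure, rasterizes a lung ellipsoid of the true volume painted at
#' the true lung intensity, places 50 mL water and muscle reference tubes
#' and an air background floor, optionally adds Rician noise, and measures
#' the observable sample table through the package's own imaging pipeline
#' (mask volumetry, mean signal, spherical reference ROIs). Optionally
#' writes NIfTI volumes/masks, ROI YAML and the CSV tables to \code{dir}.
#'
#' Lung ellipsoid axis ratios are fixed (1 : 1.15 : 1.4); reference tubes
#' are cylinders of 50 mL beside the sample.
#'
#' @param config an [exvivo_config()].
#' @param seed RNG seed.
#' @param dir optional output directory.
#' @param write_dicom also write each volume as a DICOM series (only
#'   meaningful with \code{dir}).
#' @return list with \code{samples} (pipeline-measured table),
#'   \code{truth} (analytic table as in [simulate_exvivo_samples()] plus
#'   per-scan painted intensities), and \code{scans}: per scan the
#'   \code{mri_volume}, lung \code{mri_mask} and reference
#'   \code{roi_spec}s.
#' @export
generate_exvivo_dataset <- function(config = exvivo_config(), seed = 1L,
                                    dir = NULL, write_dicom = FALSE) {
  cfg <- config
  base <- simulate_exvivo_samples(cfg, seed)
  truth <- base$truth$table
  ids <- unique(truth$sample_id)
  groups <- base$samples$group[match(ids, base$samples$sample_id)]
  gains <- truth$session_gain[match(ids, truth$sample_id)]

  tube_r <- 12.5; tube_h <- 50000 / (pi * tube_r^2)  # 50 mL cylinder
  scans <- list(); measured <- list()
  for (i in seq_along(ids)) {
    for (p in unique(truth$cpap_cmh2o)) {
      tr <- truth[truth$sample_id == ids[i] & truth$cpap_cmh2o == p, ]
      v_mm3 <- tr$volume_ml * 1000
      c_semi <- (v_mm3 / (4 / 3 * pi * 1.15 * 1.4))^(1 / 3)
      semi <- c_semi * c(1, 1.15, 1.4)
      margin <- 8
      air_zone <- 26  # empty region above everything for the air ROI
      zmax <- max(semi[3L], tube_h / 2)
      x_span <- 2 * semi[1L] + 4 * (tube_r + margin) + 2 * margin
      y_span <- 2 * max(semi[2L], tube_r) + 2 * margin
      z_span <- 2 * (zmax + margin) + air_zone
      dims <- pmax(4L, ceiling(c(x_span, y_span, z_span) / cfg$spacing))
      origin <- c(-(dims[1:2] - 1) * cfg$spacing[1:2] / 2, -(zmax + margin))
      lung_c <- c(0, 0, 0)
      tube_x <- semi[1L] + tube_r + margin
      lung_sel <- rasterize_ellipsoid(dims, cfg$spacing, origin, lung_c, semi)

      grid_x <- origin[1L] + (seq_len(dims[1L]) - 1) * cfg$spacing[1L]
      grid_y <- origin[2L] + (seq_len(dims[2L]) - 1) * cfg$spacing[2L]
      grid_z <- origin[3L] + (seq_len(dims[3L]) - 1) * cfg$spacing[3L]
      in_tube <- function(x0) {
        inxy <- outer((grid_x - x0)^2, grid_y^2, `+`) <= tube_r^2
        inz <- abs(grid_z) <= tube_h / 2
        outer(inxy, inz, `&`)
      }
      water_sel <- in_tube(-tube_x)
      muscle_sel <- in_tube(tube_x)

      lung_gu <- tr$signal_normalized * cfg$muscle_gu * gains[i]
      vox <- array(cfg$air_floor_gu, dims)
      vox[water_sel] <- cfg$water_gu * gains[i]
      vox[muscle_sel] <- cfg$muscle_gu * gains[i]
      vox[lung_sel] <- lung_gu
      vol <- mri_volume(vox, spacing = cfg$spacing, origin = origin)
      if (cfg$noise_sigma_gu > 0)
        vol <- add_rician_noise(vol, cfg$noise_sigma_gu)
      mask <- mri_mask(lung_sel, vol)

      roi_v <- 2.03
      air_center <- c(0, 0, zmax + margin + air_zone / 2)
      rois <- list(
        water = roi_spec("sphere", c(-tube_x, 0, 0), size_cm3 = roi_v),
        muscle = roi_spec("sphere", c(tube_x, 0, 0), size_cm3 = roi_v),
        air = roi_spec("sphere", air_center, size_cm3 = roi_v))

      key <- sprintf("%s_cpap%02d", ids[i], p)
      scans[[key]] <- list(volume = vol, mask = mask, rois = rois,
                           sample_id = ids[i], cpap_cmh2o = p)
      measured[[key]] <- data.frame(
        sample_id = ids[i], group = groups[i], cpap_cmh2o = p,
        mass_g = base$truth$mass_g[[ids[i]]],
        volume_ml = mask_volume_ml(mask),
        mean_signal_gu = mean_signal(vol, mask),
        water_ref_gu = sample_roi(vol, rois$water),
        muscle_ref_gu = sample_roi(vol, rois$muscle),
        air_ref_gu = sample_roi(vol, rois$air),
        evlw_g_per_g = base$samples$evlw_g_per_g[
          match(ids[i], base$samples$sample_id)])
      if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        write_nifti_volume(vol, file.path(dir, paste0(key, ".nii.gz")))
        write_nifti_volume(mask, file.path(dir, paste0(key, "_mask.nii.gz")))
        write_roi_config(rois, file.path(dir, paste0(key, "_rois.yaml")))
        if (write_dicom)
          write_dicom_series(vol, file.path(dir, paste0(key, "_dicom")))
      }
    }
  }
  samples <- do.call(rbind, measured)
  rownames(samples) <- NULL
  if (!is.null(dir)) {
    write_sample_table(samples, file.path(dir, "samples_measured.csv"))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(samples = samples, truth = base$truth, scans = scans)
}
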