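#' Lung density from gravimetric mass and MRI volume
#'
#' Density of a lung sample as scale mass over MRI-segmented volume,
#' in g/mL.
#'
#' @param mass_g tissue mass (g), after removal of large airways.
#' @param volume_ml segmented lung volume (mL) at the same inflation level.
#' @return Density in g/mL. Vectorized.
#' @examples
#' compute_density(100, 100)   # 1 g/mL
#' compute_density(93.6, 120)  # 0.78 g/mL
#' @export
compute_density <- function(mass_g, volume_ml) {
  if (any(volume_ml <= 0)) stop("'volume_ml' must be positive")
  if (any(mass_g <= 0)) stop("'mass_g' must be positive")
  mass_g / volume_ml
}

#' Gas fraction from inflated and deflated lung volumes
#'
#' \code{GAS_F = (V_CPAP - V_0) / V_CPAP}: the fraction of the current lung
#' volume that is gas, taking the fully deflated volume V_0 as the tissue
#' (gas-free) reference. Zero when fully deflated, approaching 1 at extreme
#' inflation; slightly negative values can occur through volumetry noise at
#' low pressures and are returned as-is (values below -0.05 are clamped to
#' -0.05 with a warning).
#'
#' @param v_cpap_ml lung volume (mL) at the current airway pressure.
#' @param v0_ml deflated reference volume (mL) at zero airway pressure.
#' @return Gas fraction (dimensionless), always < 1. Vectorized.
#' @export
compute_gas_fraction <- function(v_cpap_ml, v0_ml) {
  if (any(v_cpap_ml <= 0)) stop("'v_cpap_ml' must be positive")
  if (any(v0_ml <= 0)) stop("'v0_ml' must be positive")
  gf <- (v_cpap_ml - v0_ml) / v_cpap_ml
  low <- gf < -0.05
  if (any(low)) {
    warning(sprintf("%d gas fraction(s) below -0.05 clamped (volumetry inconsistent?)",
                    sum(low)))
    gf[low] <- -0.05
  }
  gf
}

#' MRI signal attenuation factor
#'
#' \code{MRI_ATT = MRI_CPAP / MRI_0}: a sample's mean signal at a given
#' inflation relative to its own fully deflated signal. Equal to 1 at zero
#' airway pressure by construction, and invariant to normalization by a
#' reference shared between the two scans (the scalar cancels).
#'
#' @param mri_cpap_gu mean lung signal at the current pressure (GU or
#'   normalized).
#' @param mri0_gu mean lung signal fully deflated, same units; > 0.
#' @return Attenuation factor (dimensionless). Vectorized.
#' @export
compute_attenuation <- function(mri_cpap_gu, mri0_gu) {
  if (any(mri0_gu <= 0)) stop("'mri0_gu' must be positive")
  mri_cpap_gu / mri0_gu
}

sample_table_columns <- c("sample_id", "group", "cpap_cmh2o", "mass_g",
                          "volume_ml", "mean_signal_gu", "water_ref_gu",
                          "muscle_ref_gu", "air_ref_gu")

#' Validate an ex vivo sample table
#'
#' The long-format table holds one row per (sample, airway pressure):
#' columns \code{sample_id}, \code{group} ("healthy"/"injured"),
#' \code{cpap_cmh2o}, \code{mass_g}, \code{volume_ml},
#' \code{mean_signal_gu}, \code{water_ref_gu}, \code{muscle_ref_gu},
#' \code{air_ref_gu}, and optionally \code{evlw_g_per_g} for injured
#' samples. Every sample must have a 0 cmH2O row (the deflated reference).
#'
#' @param samples data.frame in the above layout.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_sample_table <- function(samples) {
  missing_cols <- setdiff(sample_table_columns, names(samples))
  if (length(missing_cols) > 0L)
    stop("sample table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(samples$group %in% c("healthy", "injured")))
    stop("'group' must be 'healthy' or 'injured'")
  if (any(samples$mass_g <= 0)) stop("'mass_g' must be positive")
  if (any(samples$volume_ml <= 0)) stop("'volume_ml' must be positive")
  has_ref <- tapply(samples$cpap_cmh2o == 0, samples$sample_id, any)
  if (!all(has_ref))
    stop("sample(s) lacking a 0 cmH2O deflated reference row: ",
         paste(names(has_ref)[!has_ref], collapse = ", "))
  invisible(samples)
}

#' Read / write ex vivo sample tables as CSV
#'
#' @param path CSV path.
#' @return \code{read_sample_table}: validated data.frame.
#' @seealso [validate_sample_table()] for the column layout.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  samples <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_table(samples)
  samples
}

#' @rdname read_sample_table
#' @param samples sample table data.frame.
#' @export
write_sample_table <- function(samples, path) {
  validate_sample_table(samples)
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

## normalized mean lung signal for one normalization choice
normalized_signal <- function(samples, normalization) {
  switch(normalization,
         none = samples$mean_signal_gu,
         water = {
           if (any(samples$water_ref_gu <= 0)) stop("water reference must be positive")
           samples$mean_signal_gu / samples$water_ref_gu
         },
         muscle = {
           if (any(samples$muscle_ref_gu <= 0)) stop("muscle reference must be positive")
           samples$mean_signal_gu / samples$muscle_ref_gu
         },
         stop("unknown normalization: ", normalization))
}

#' Per-observation attenuation/gas-fraction table
#'
#' Derives, for each sample and airway pressure, the gas fraction relative
#' to the deflated scan and the signal attenuation factor on the chosen
#' normalization scale. Deflated rows (0 cmH2O) are flagged as
#' \code{reference}: they sit at (0, 1) by construction.
#'
#' @param samples ex vivo sample table (see [validate_sample_table()]).
#' @param normalization \code{"water"}, \code{"muscle"} or \code{"none"}.
#' @return data.frame with columns \code{sample_id}, \code{group},
#'   \code{cpap_cmh2o}, \code{gas_fraction}, \code{attenuation},
#'   \code{reference}.
#' @export
attenuation_table <- function(samples,
                              normalization = c("water", "muscle", "none")) {
  normalization <- match.arg(normalization)
  validate_sample_table(samples)
  x <- normalized_signal(samples, normalization)
  out <- do.call(rbind, lapply(split(seq_len(nrow(samples)), samples$sample_id),
    function(idx) {
      rows <- samples[idx, ]
      ref <- which(rows$cpap_cmh2o == 0)[1L]
      data.frame(sample_id = rows$sample_id,
                 group = rows$group,
                 cpap_cmh2o = rows$cpap_cmh2o,
                 gas_fraction = compute_gas_fraction(rows$volume_ml,
                                                     rows$volume_ml[ref]),
                 attenuation = compute_attenuation(x[idx], x[idx][ref]),
                 reference = seq_along(idx) == ref)
    }))
  rownames(out) <- NULL
  out
}

#' Descriptive statistics of the ex vivo samples
#'
#' Mean and population standard deviation (divisor n, not n-1) of sample
#' mass, and of the retained extravascular lung water (EVLW) fraction over
#' the injured samples. The population convention is used deliberately for
#' these sample-characteristic summaries.
#'
#' @param samples sample table, or any data.frame with one row per sample
#'   carrying \code{sample_id}, \code{mass_g}, \code{group} and optionally
#'   \code{evlw_g_per_g}; repeated per-pressure rows are collapsed by
#'   \code{sample_id}.
#' @return list with \code{mass_mean_g}, \code{mass_sd_g},
#'   \code{evlw_mean}, \code{evlw_sd}, \code{n_samples},
#'   \code{n_injured}.
#' @export
descriptive_stats <- function(samples) {
  if (nrow(samples) < 1L) stop("need at least one sample")
  per <- samples[!duplicated(samples$sample_id), , drop = FALSE]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  evlw <- if ("evlw_g_per_g" %in% names(per))
    per$evlw_g_per_g[per$group == "injured" & !is.na(per$evlw_g_per_g)]
  else numeric(0)
  list(mass_mean_g = mean(per$mass_g),
       mass_sd_g = pop_sd(per$mass_g),
       evlw_mean = if (length(evlw)) mean(evlw) else NA_real_,
       evlw_sd = if (length(evlw)) pop_sd(evlw) else NA_real_,
       n_samples = nrow(per),
       n_injured = sum(per$group == "injured"))
}

#' Sample size to detect a correlation
#'
#' Smallest n for a two-sided test of a Pearson correlation via the Fisher
#' z transform: \code{n = ceil(((z_{a/2} + z_beta) / atanh(r))^2 + 3)}.
#'
#' @param r expected correlation, 0 < |r| < 1.
#' @param alpha two-sided significance level.
#' @param power target power (1 - beta).
#' @return Required number of samples (integer).
#' @examples
#' sample_size_for_correlation(0.8, 0.05, 0.90)  # 12
#' @export
sample_size_for_correlation <- function(r, alpha = 0.05, power = 0.90) {
  if (abs(r) >= 1 || abs(r) <= 0) stop("need 0 < |r| < 1")
  if (alpha <= 0 || alpha >= 1) stop("need 0 < alpha < 1")
  if (power <= 0 || power >= 1) stop("need 0 < power < 1")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling((z / atanh(abs(r)))^2 + 3))
}
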