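#' Configuration for the in vivo thorax phantom
#'
#' Describes a supine thorax phantom acquired as two or three contiguous
#' axial blocks with independent scanner gain: an elliptical body with a
#' posterior muscle band, two lung ellipsoids carrying a ventro-dorsal
#' (anterior-to-posterior) intensity gradient, and an optional dorsal
#' atelectasis region painted at a fixed muscle-normalized intensity. The
#' painted intensity histogram realizes exact target compartment
#' fractions: the most dorsal voxels of the left lung form the
#' atelectasis (non-aerated class), the next most dorsal lung voxels span
#' the poorly aerated intensity band, and the rest the normally aerated
#' band, each band kept clear of the classification thresholds by
#' \code{band_margin} so the noiseless phantom classifies exactly.
#'
#' @param spacing voxel spacing (mm).
#' @param nx,ny in-plane grid size.
#' @param n_blocks number of acquisition blocks (2 or 3).
#' @param nz_per_block axial slices per block.
#' @param body_semi_mm body ellipse semi-axes (x, y) in mm.
#' @param lung_center_x_mm lateral offset of each lung centre (mm).
#' @param lung_semi_mm lung ellipsoid semi-axes (mm).
#' @param frac_nonaerated,frac_poor target compartment fractions of total
#'   lung volume; must sum to at most 1.
#' @param atelectasis logical; without it the non-aerated fraction is 0.
#' @param atel_intensity muscle-normalized intensity of atelectasis.
#' @param thresholds numeric (non-aerated, poor) classification thresholds
#'   on the muscle-normalized scale used to position the painted bands.
#' @param band_margin gap (normalized units) between painted bands and the
#'   thresholds.
#' @param ventral_level lowest normalized intensity of the most ventral
#'   normally aerated voxels.
#' @param soft_tissue_norm normalized intensity of non-muscle soft tissue.
#' @param muscle_gu muscle signal (GU) before block gain.
#' @param block_gains per-block scanner gain (length \code{n_blocks}).
#' @param air_floor_gu background air intensity floor (GU).
#' @param noise_sigma Rician noise SD on the muscle-normalized scale
#'   (applied to raw intensities as \code{noise_sigma * muscle_gu}).
#' @return A validated list of class \code{invivo_config}.
#' @export
invivo_config <- function(spacing = c(2.5, 2.5, 4),
                          nx = 72L, ny = 60L,
                          n_blocks = 3L, nz_per_block = 12L,
                          body_semi_mm = c(80, 70),
                          lung_center_x_mm = 40,
                          lung_semi_mm = c(30, 40, 65),
                          frac_nonaerated = 0.10, frac_poor = 0.16,
                          atelectasis = TRUE, atel_intensity = 0.92,
                          thresholds = c(nonaerated = 0.644, poor = 0.2576),
                          band_margin = 0.10, ventral_level = 0.08,
                          soft_tissue_norm = 1.05,
                          muscle_gu = 600,
                          block_gains = c(1, 1.12, 0.95),
                          air_floor_gu = 2,
                          noise_sigma = 0) {
  if (!n_blocks %in% 2:3) stop("'n_blocks' must be 2 or 3")
  if (length(block_gains) < n_blocks) stop("need one gain per block")
  block_gains <- block_gains[seq_len(n_blocks)]
  if (frac_nonaerated < 0 || frac_poor < 0 ||
      frac_nonaerated + frac_poor > 1)
    stop("compartment fractions must be in [0, 1] and sum to at most 1")
  if (thresholds[1L] <= thresholds[2L])
    stop("'thresholds' must be (non-aerated, poor) with non-aerated larger")
  if (thresholds[2L] - band_margin <= ventral_level)
    stop("poor threshold minus band_margin must exceed ventral_level")
  if (atel_intensity <= thresholds[1L] + band_margin / 2)
    stop("'atel_intensity' must sit clearly above the non-aerated threshold")
  structure(as.list(environment()), class = "invivo_config")
}

#' Generate an in vivo thorax phantom as acquisition blocks
#'
#' Builds the phantom described by [invivo_config()] and emits it the way
#' a scanner would: as \code{n_blocks} contiguous axial blocks in raw grey
#' units with per-block gain, plus the lung mask, per-block muscle ROI
#' specifications (0.46 cm^2 disc in each block's middle slice), the
#' atelectasis cube ROI (2.03 cm^3, at the centroid of the painted
#' atelectasis, when present) and the ground truth.
#'
#' @param config an [invivo_config()].
#' @param seed RNG seed (noise only; geometry is deterministic).
#' @return list with \code{blocks} (list of raw \code{mri_volume}),
#'   \code{mask} (lung \code{mri_mask} on the merged grid),
#'   \code{muscle_rois} (per block, slice index local to the block),
#'   \code{atel_roi} (or NULL), and \code{truth}: painted normalized
#'   volume, per-class voxel counts and fractions, total lung volume,
#'   ventral/dorsal painted means, config and seed.
#' @export
generate_invivo_scan <- function(config = invivo_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  nz <- cfg$n_blocks * cfg$nz_per_block
  dims <- c(cfg$nx, cfg$ny, nz)
  origin <- -(dims - 1) * cfg$spacing / 2
  geom <- mri_volume(array(0, dims), spacing = cfg$spacing, origin = origin)

  gx <- axis_coords(geom, 1L); gy <- axis_coords(geom, 2L)
  body2d <- outer((gx / cfg$body_semi_mm[1L])^2,
                  (gy / cfg$body_semi_mm[2L])^2, `+`) <= 1
  body <- array(body2d, dims)

  lung_l <- rasterize_ellipsoid(dims, cfg$spacing, origin,
                                c(-cfg$lung_center_x_mm, 0, 0),
                                cfg$lung_semi_mm)
  lung_r <- rasterize_ellipsoid(dims, cfg$spacing, origin,
                                c(cfg$lung_center_x_mm, 0, 0),
                                cfg$lung_semi_mm)
  lung <- lung_l | lung_r
  n_lung <- sum(lung)
  if (n_lung < 100L) stop("lung region too small; enlarge the grid")

  ## posterior muscle band: a slab just inside the dorsal body wall
  y_band <- gy >= cfg$body_semi_mm[2L] - 18 & gy <= cfg$body_semi_mm[2L] - 4
  muscle_band <- body & array(rep(y_band, each = cfg$nx), dims)
  muscle_band <- muscle_band & !lung

  ## painted normalized field
  field <- array(0, dims)
  field[body] <- cfg$soft_tissue_norm
  field[muscle_band] <- 1

  idx <- which(lung, arr.ind = TRUE)
  yw <- origin[2L] + (idx[, 2L] - 1) * cfg$spacing[2L]
  left <- idx[, 1L] <= (cfg$nx + 1) / 2
  ord_key <- order(yw, idx[, 1L], idx[, 3L])  # ventral -> dorsal, deterministic

  n_non <- if (cfg$atelectasis) round(cfg$frac_nonaerated * n_lung) else 0L
  n_poor <- round(cfg$frac_poor * n_lung)
  if (n_non > sum(left))
    stop("atelectasis does not fit in the left lung at this fraction")

  lin <- function(ii) idx[ii, 1L] + (idx[ii, 2L] - 1L) * dims[1L] +
    (idx[ii, 3L] - 1L) * dims[1L] * dims[2L]

  atel_rows <- integer(0)
  if (n_non > 0L) {
    left_rows <- which(left)
    atel_rows <- left_rows[order(-yw[left_rows], idx[left_rows, 1L],
                                 idx[left_rows, 3L])][seq_len(n_non)]
    field[lin(atel_rows)] <- cfg$atel_intensity
  }
  rest <- setdiff(seq_len(nrow(idx)), atel_rows)
  rest <- rest[order(yw[rest], idx[rest, 1L], idx[rest, 3L])]  # ventral first
  n_rest <- length(rest)
  n_poor <- min(n_poor, n_rest)
  poor_rows <- if (n_poor > 0L) rest[(n_rest - n_poor + 1L):n_rest] else integer(0)
  norm_rows <- if (n_poor < n_rest) rest[seq_len(n_rest - n_poor)] else integer(0)
  t_non <- cfg$thresholds[[1L]]; t_poor <- cfg$thresholds[[2L]]
  ramp <- function(n, lo, hi) if (n == 1L) (lo + hi) / 2 else
    seq(lo, hi, length.out = n)
  if (length(poor_rows) > 0L)
    field[lin(poor_rows)] <- ramp(length(poor_rows),
                                  t_poor + cfg$band_margin,
                                  t_non - cfg$band_margin)
  if (length(norm_rows) > 0L)
    field[lin(norm_rows)] <- ramp(length(norm_rows),
                                  cfg$ventral_level,
                                  t_poor - cfg$band_margin)

  ## atelectasis reference ROI at the centroid of the painted region
  atel_roi <- NULL
  if (n_non > 0L) {
    ctr <- origin + (colMeans(idx[atel_rows, , drop = FALSE]) - 1) * cfg$spacing
    atel_roi <- roi_spec("cube", ctr, size_cm3 = 2.03)
    cube_sel <- roi_voxels(geom, atel_roi)
    atel_mask <- array(FALSE, dims); atel_mask[lin(atel_rows)] <- TRUE
    if (any(cube_sel & !atel_mask))
      stop("atelectasis region cannot contain the 2.03 cm^3 reference cube; ",
           "increase frac_nonaerated or the lung size")
  }

  ## emit as raw blocks with per-block gain and muscle disc ROIs
  blocks <- list(); muscle_rois <- list()
  sigma_raw <- cfg$noise_sigma * cfg$muscle_gu
  for (b in seq_len(cfg$n_blocks)) {
    zs <- (b - 1L) * cfg$nz_per_block + seq_len(cfg$nz_per_block)
    raw <- field[, , zs, drop = FALSE] * cfg$muscle_gu * cfg$block_gains[b]
    raw[raw == 0] <- cfg$air_floor_gu
    bvol <- mri_volume(raw, spacing = cfg$spacing,
                       origin = c(origin[1:2],
                                  origin[3L] + (zs[1L] - 1) * cfg$spacing[3L]))
    if (sigma_raw > 0) bvol <- add_rician_noise(bvol, sigma_raw)
    mid <- ceiling(cfg$nz_per_block / 2)
    muscle_rois[[b]] <- roi_spec("disc",
                                 c(0, cfg$body_semi_mm[2L] - 11,
                                   axis_coords(bvol, 3L)[mid]),
                                 size_cm2 = 0.46, slice_index = mid)
    blocks[[b]] <- bvol
  }

  mask <- mri_mask(lung, geom)
  truth_vol <- mri_volume(field, spacing = cfg$spacing, origin = origin)
  halves <- ventro_dorsal_split(mask)
  counts <- c(nonaerated = n_non, poorly_aerated = length(poor_rows),
              normally_aerated = length(norm_rows))
  list(blocks = blocks, mask = mask, muscle_rois = muscle_rois,
       atel_roi = atel_roi,
       truth = list(
         normalized_volume = truth_vol,
         class_counts = counts,
         class_fractions = counts / n_lung,
         total_lung_volume_ml = n_lung * prod(cfg$spacing) / 1000,
         ventral_mean = mean_signal(truth_vol, halves$ventral),
         dorsal_mean = mean_signal(truth_vol, halves$dorsal),
         config = cfg, seed = seed))
}
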