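#' Mask volume in millilitres
#'
#' Segmented volume as voxel count times voxel volume, the standard
#' volumetry used for total lung volume (TLV) and compartment volumes.
#'
#' @param mask an \code{mri_mask} (or an \code{mri_volume} whose data are
#'   interpreted as non-zero = inside).
#' @return Volume in mL (1 mL = 1000 mm^3); 0 for an empty mask.
#' @examples
#' v <- mri_volume(array(0, c(10, 10, 10)))
#' m <- mri_mask(array(TRUE, c(10, 10, 10)), v)
#' mask_volume_ml(m)  # 1 mL
#' @export
mask_volume_ml <- function(mask) {
  n <- sum(mask$data != 0)
  n * voxel_volume_mm3(mask) / 1000
}

#' Mean signal under a mask
#'
#' Arithmetic mean of volume intensities over the masked voxels, in grey
#' units — the per-sample summary signal used throughout the calibration.
#'
#' @param volume an \code{mri_volume}.
#' @param mask an \code{mri_mask} on the same grid; must be non-empty.
#' @return Mean intensity (GU).
#' @export
mean_signal <- function(volume, mask) {
  stopifnot_same_grid(volume, mask)
  n <- sum(mask$data)
  if (n == 0L) stop("mask is empty: mean signal undefined")
  mean(volume$data[mask$data])
}

#' Normalize signal to a reference
#'
#' Divides signal by a reference-tissue signal (water or muscle), turning
#' uncalibrated grey units into a dimensionless ratio comparable across
#' scans. Works voxel-wise on a volume or on scalar means; for a fixed
#' scalar reference the two commute.
#'
#' @param signal numeric scalar/array or an \code{mri_volume}.
#' @param reference positive scalar reference signal (GU).
#' @return Same shape as \code{signal}, divided by \code{reference}.
#' @export
normalize_signal <- function(signal, reference) {
  if (!is.numeric(reference) || length(reference) != 1L ||
      !is.finite(reference) || reference <= 0)
    stop("'reference' must be a single positive value")
  if (inherits(signal, "mri_volume")) {
    signal$data <- signal$data / reference
    signal
  } else {
    signal / reference
  }
}

#' Signal-to-noise ratio
#'
#' SNR defined as mean lung signal over mean background-air signal. In
#' magnitude images the air region carries Rician (Rayleigh) noise, so the
#' air mean is strictly positive.
#'
#' @param lung_signal mean lung signal (GU).
#' @param air_signal mean air/background ROI signal (GU), > 0.
#' @return Dimensionless ratio.
#' @export
snr <- function(lung_signal, air_signal) {
  if (!is.numeric(air_signal) || length(air_signal) != 1L || air_signal <= 0)
    stop("'air_signal' must be a single positive value")
  lung_signal / air_signal
}

#' Merge apnoea acquisition blocks into one normalized volume
#'
#' Whole-thorax scans are acquired as two or three contiguous blocks along
#' the inferior-superior axis, one breath-hold each, with independent
#' scanner gain. Each block is divided by its own muscle reference signal
#' before concatenation, so the merged volume is in muscle-normalized units
#' and per-block gain cancels.
#'
#' @param blocks list of \code{mri_volume}, ordered inferior to superior,
#'   sharing in-plane grid and spacing and contiguous along axis 3.
#' @param block_muscle_refs numeric, one positive muscle reference (GU) per
#'   block.
#' @return A single \code{mri_volume} in muscle-normalized units.
#' @export
merge_blocks <- function(blocks, block_muscle_refs) {
  if (!is.list(blocks) || length(blocks) < 1L)
    stop("'blocks' must be a non-empty list of volumes")
  if (length(block_muscle_refs) != length(blocks))
    stop("need exactly one muscle reference per block")
  if (any(block_muscle_refs <= 0)) stop("muscle references must be positive")
  b1 <- blocks[[1L]]
  for (b in blocks) {
    if (!inherits(b, "mri_volume")) stop("each block must be an mri_volume")
    if (!identical(dim(b$data)[1:2], dim(b1$data)[1:2]))
      stop("blocks differ in in-plane grid size")
    if (max(abs(b$spacing - b1$spacing)) > 1e-6)
      stop("blocks differ in voxel spacing")
    if (max(abs(b$origin[1:2] - b1$origin[1:2])) > 1e-6)
      stop("blocks differ in in-plane origin")
  }
  ## contiguity along inferior-superior axis: each block must start one
  ## voxel after the previous block's last slice
  z_end <- b1$origin[3L] + (dim(b1$data)[3L] - 1) * b1$spacing[3L]
  if (length(blocks) > 1L) {
    for (i in 2:length(blocks)) {
      expected <- z_end + blocks[[i]]$spacing[3L]
      if (abs(blocks[[i]]$origin[3L] - expected) > 0.01 * blocks[[i]]$spacing[3L]) {
        if (blocks[[i]]$origin[3L] < expected)
          stop(sprintf("block %d overlaps the previous block", i))
        stop(sprintf("block %d is not contiguous with the previous block", i))
      }
      z_end <- blocks[[i]]$origin[3L] +
        (dim(blocks[[i]]$data)[3L] - 1) * blocks[[i]]$spacing[3L]
    }
  }
  normalized <- mapply(function(b, ref) b$data / ref, blocks,
                       block_muscle_refs, SIMPLIFY = FALSE)
  merged <- array(0, c(dim(b1$data)[1:2],
                       sum(vapply(blocks, function(b) dim(b$data)[3L], 1L))))
  k <- 0L
  for (nd in normalized) {
    merged[, , k + seq_len(dim(nd)[3L])] <- nd
    k <- k + dim(nd)[3L]
  }
  mri_volume(merged, spacing = b1$spacing, origin = b1$origin)
}
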