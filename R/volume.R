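#' 3D MRI volume with voxel geometry
#'
#' Container for a magnitude MRI volume: a 3D array of non-negative
#' intensities in grey units (GU) plus the voxel geometry needed to work in
#' world (scanner) millimetre coordinates. The grid axes carry fixed
#' anatomical labels: axis 1 runs right to left, axis 2 anterior to
#' posterior (so increasing index = more dorsal in a supine subject), axis 3
#' inferior to superior. The world coordinate of voxel \code{(i, j, k)}
#' (1-based) is \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' Magnitude images cannot be negative; negative input intensities are
#' clamped to zero with a warning.
#'
#' @param data numeric 3D array of intensities (GU).
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, world coordinate (mm) of the first voxel
#'   centre.
#' @return An object of class \code{mri_volume}: a list with elements
#'   \code{data}, \code{spacing}, \code{origin}, \code{axes}.
#' @examples
#' v <- mri_volume(array(1, c(4, 4, 2)), spacing = c(1.37, 1.37, 4))
#' v
#' @export
mri_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  if (anyNA(data)) stop("volume intensities contain NA")
  if (any(data < 0)) {
    warning(sprintf("clamped %d negative intensities to 0 (magnitude image)",
                    sum(data < 0)))
    data[data < 0] <- 0
  }
  structure(
    list(data = data, spacing = spacing, origin = origin,
         axes = c("right-left", "anterior-posterior", "inferior-superior")),
    class = "mri_volume")
}

#' Binary mask paired with a volume's geometry
#'
#' A mask stores no independent geometry: it inherits spacing/origin/axes
#' from the volume (or mask) it is paired with, which makes geometry
#' mismatch between a volume and its segmentation unrepresentable.
#'
#' @param data logical (or 0/1 numeric) 3D array.
#' @param geometry an \code{mri_volume} (or \code{mri_mask}) supplying
#'   spacing, origin and grid shape; the mask grid must match it exactly.
#' @return An object of class \code{c("mri_mask", "mri_volume")} with
#'   logical \code{data}.
#' @export
mri_mask <- function(data, geometry) {
  if (!inherits(geometry, "mri_volume"))
    stop("'geometry' must be an mri_volume")
  if (is.numeric(data)) data <- data != 0
  if (!is.logical(data) || length(dim(data)) != 3L)
    stop("'data' must be a logical 3D array")
  if (!identical(dim(data), dim(geometry$data)))
    stop("mask grid shape does not match the paired volume")
  structure(
    list(data = data, spacing = geometry$spacing, origin = geometry$origin,
         axes = geometry$axes),
    class = c("mri_mask", "mri_volume"))
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm\n",
              class(x)[1L], d[1L], d[2L], d[3L],
              paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (mm): %s\n", paste(signif(x$origin, 4), collapse = ", ")))
  if (inherits(x, "mri_mask")) {
    cat(sprintf("  %d voxels in mask (%.2f mL)\n", sum(x$data), mask_volume_ml(x)))
  } else {
    cat(sprintf("  intensity range [%.4g, %.4g] GU\n",
                min(x$data), max(x$data)))
  }
  invisible(x)
}

## voxel volume in mm^3
voxel_volume_mm3 <- function(x) prod(x$spacing)

## world coordinates (mm) of voxel centres along one axis
axis_coords <- function(x, axis) {
  x$origin[axis] + (seq_len(dim(x$data)[axis]) - 1) * x$spacing[axis]
}

stopifnot_same_grid <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("volume and mask grids differ in shape")
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9)
    stop("volume and mask voxel spacing differ")
}
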