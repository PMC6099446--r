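#' Analytic region-of-interest specification
#'
#' Reference signals (water, muscle, air, atelectasis) are sampled from
#' analytic ROIs placed in world coordinates: a sphere or cube specified by
#' its volume in cm^3, or a disc of given area in cm^2 lying in a single
#' axial slice (the in-slice muscle ROI used on thorax blocks). Linear
#' dimensions are derived from the size: sphere radius \code{(3V/4pi)^(1/3)},
#' cube side \code{V^(1/3)}, disc radius \code{sqrt(A/pi)}.
#'
#' @param shape one of \code{"sphere"}, \code{"cube"}, \code{"disc"}.
#' @param center_mm world coordinate (mm) of the ROI centre, length 3.
#' @param size_cm3 volume in cm^3 (sphere, cube).
#' @param size_cm2 area in cm^2 (disc).
#' @param slice_index axial (axis 3) slice index for a disc ROI.
#' @return An object of class \code{roi_spec}.
#' @examples
#' roi_spec("sphere", c(0, 0, 0), size_cm3 = 2.03)  # radius 7.85 mm
#' roi_spec("disc", c(0, 0, 0), size_cm2 = 0.46, slice_index = 5)
#' @export
roi_spec <- function(shape = c("sphere", "cube", "disc"), center_mm,
                     size_cm3 = NULL, size_cm2 = NULL, slice_index = NULL) {
  shape <- match.arg(shape)
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 3L || anyNA(center_mm))
    stop("'center_mm' must be 3 finite world coordinates")
  if (shape == "disc") {
    if (is.null(size_cm2) || size_cm2 <= 0)
      stop("disc ROI requires 'size_cm2' > 0")
    if (is.null(slice_index) || slice_index < 1)
      stop("disc ROI requires a valid 'slice_index'")
    radius <- sqrt(size_cm2 * 100 / pi)  # cm^2 -> mm^2
  } else {
    if (is.null(size_cm3) || size_cm3 <= 0)
      stop(sprintf("%s ROI requires 'size_cm3' > 0", shape))
    radius <- if (shape == "sphere") (3 * size_cm3 * 1000 / (4 * pi))^(1 / 3)
              else size_cm3^(1 / 3) * 10 / 2  # half-side, mm
  }
  structure(list(shape = shape, center_mm = center_mm,
                 size_cm3 = size_cm3, size_cm2 = size_cm2,
                 slice_index = if (shape == "disc") as.integer(slice_index),
                 radius_mm = radius),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  dim_lab <- if (x$shape == "cube") sprintf("side %.2f mm", 2 * x$radius_mm)
             else sprintf("radius %.2f mm", x$radius_mm)
  cat(sprintf("<roi_spec> %s, %s, centre (%s) mm%s\n", x$shape, dim_lab,
              paste(signif(x$center_mm, 4), collapse = ", "),
              if (x$shape == "disc") sprintf(", slice %d", x$slice_index) else ""))
  invisible(x)
}

## logical array of voxels whose centres fall inside the ROI
roi_voxels <- function(volume, roi) {
  d <- dim(volume$data)
  cx <- axis_coords(volume, 1L)
  cy <- axis_coords(volume, 2L)
  cz <- axis_coords(volume, 3L)
  sel <- array(FALSE, d)
  if (roi$shape == "sphere") {
    dx2 <- (cx - roi$center_mm[1L])^2
    dy2 <- (cy - roi$center_mm[2L])^2
    dz2 <- (cz - roi$center_mm[3L])^2
    r2 <- roi$radius_mm^2
    sel <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2
    lo <- roi$center_mm - roi$radius_mm
    hi <- roi$center_mm + roi$radius_mm
  } else if (roi$shape == "cube") {
    inx <- abs(cx - roi$center_mm[1L]) <= roi$radius_mm
    iny <- abs(cy - roi$center_mm[2L]) <= roi$radius_mm
    inz <- abs(cz - roi$center_mm[3L]) <= roi$radius_mm
    sel <- outer(outer(inx, iny, `&`), inz, `&`)
    lo <- roi$center_mm - roi$radius_mm
    hi <- roi$center_mm + roi$radius_mm
  } else {  # disc in one axial slice
    if (roi$slice_index > d[3L]) stop("disc slice_index outside the volume")
    dx2 <- (cx - roi$center_mm[1L])^2
    dy2 <- (cy - roi$center_mm[2L])^2
    sel[, , roi$slice_index] <- outer(dx2, dy2, `+`) <= roi$radius_mm^2
    lo <- c(roi$center_mm[1:2] - roi$radius_mm, cz[roi$slice_index])
    hi <- c(roi$center_mm[1:2] + roi$radius_mm, cz[roi$slice_index])
  }
  bounds_lo <- volume$origin - volume$spacing / 2
  bounds_hi <- volume$origin + (d - 1 + 0.5) * volume$spacing
  if (any(lo < bounds_lo - 1e-9) || any(hi > bounds_hi + 1e-9))
    stop("ROI extends outside the volume grid")
  sel
}

#' Mean intensity of an analytic ROI
#'
#' Averages the intensities of all voxels whose centres fall inside the
#' ROI shape (voxel-centre inclusion, no partial-volume weighting).
#'
#' @param volume an \code{mri_volume}.
#' @param roi an \code{roi_spec} lying fully inside the volume bounds.
#' @return Mean intensity (GU, or dimensionless if the volume is
#'   normalized).
#' @export
sample_roi <- function(volume, roi) {
  if (!inherits(roi, "roi_spec")) stop("'roi' must be an roi_spec")
  sel <- roi_voxels(volume, roi)
  n <- sum(sel)
  if (n == 0L) stop("ROI contains no voxel centres at this grid resolution")
  mean(volume$data[sel])
}

#' Read ROI specifications from a YAML/JSON config
#'
#' Config is a named map of ROIs, each with keys \code{shape},
#' \code{center_mm}, and \code{size_cm3} or \code{size_cm2} (plus
#' \code{slice_index} for discs), e.g.
#' \preformatted{
#' muscle: {shape: disc, center_mm: [10, 80, 40], size_cm2: 0.46, slice_index: 12}
#' atelectasis: {shape: cube, center_mm: [-40, 60, 30], size_cm3: 2.03}
#' }
#'
#' @param path YAML (or JSON) file path.
#' @return Named list of \code{roi_spec}.
#' @export
read_roi_config <- function(path) {
  if (!file.exists(path)) stop("ROI config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("ROI config must be a named map of ROI entries")
  lapply(cfg, function(e) {
    roi_spec(shape = e$shape, center_mm = unlist(e$center_mm),
             size_cm3 = e$size_cm3, size_cm2 = e$size_cm2,
             slice_index = e$slice_index)
  })
}

#' Write ROI specifications to YAML
#'
#' @param rois named list of \code{roi_spec}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_roi_config <- function(rois, path) {
  out <- lapply(rois, function(r) {
    e <- list(shape = r$shape, center_mm = as.numeric(r$center_mm))
    if (!is.null(r$size_cm3)) e$size_cm3 <- r$size_cm3
    if (!is.null(r$size_cm2)) e$size_cm2 <- r$size_cm2
    if (!is.null(r$slice_index)) e$slice_index <- r$slice_index
    e
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
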