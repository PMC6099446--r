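#' Read a volume from NIfTI
#'
#' Voxel spacing is taken from the NIfTI pixdim and the world origin from
#' the sform/qform translation. The grid is used as stored; the package's
#' axis convention (right-left, anterior-posterior, inferior-superior) is
#' assumed to match the file's axis order, which holds for all volumes the
#' package itself writes.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return An \code{mri_volume}.
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  im <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(im)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("NIfTI file lacks valid voxel spacing metadata: ", path)
  xf <- try(RNifti::xform(im), silent = TRUE)
  orig <- if (!inherits(xf, "try-error") && is.matrix(xf)) xf[1:3, 4L] else c(0, 0, 0)
  a <- as.array(im)
  if (length(dim(a)) == 4L && dim(a)[4L] == 1L) a <- a[, , , 1L, drop = TRUE]
  if (length(dim(a)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  a <- array(as.double(a), dim(a))  # drop NIfTI header attributes
  mri_volume(a, spacing = sp[1:3], origin = as.numeric(orig))
}

#' Write a volume (or mask) to NIfTI
#'
#' @param volume an \code{mri_volume} or \code{mri_mask}.
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
write_nifti_volume <- function(volume, path) {
  if (!inherits(volume, "mri_volume")) stop("'volume' must be an mri_volume")
  a <- volume$data
  if (is.logical(a)) a <- array(as.double(a), dim(a))
  im <- RNifti::asNifti(a)
  RNifti::pixdim(im) <- volume$spacing
  xf <- diag(c(volume$spacing, 1))
  xf[1:3, 4L] <- volume$origin
  RNifti::sform(im) <- structure(xf, code = 2L)
  RNifti::qform(im) <- structure(xf, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a binary mask from NIfTI, paired with a volume
#'
#' The mask file must match the volume's grid and spacing; any non-zero
#' voxel is inside the mask. The returned mask inherits the volume's
#' geometry (masks carry no independent geometry).
#'
#' @param path NIfTI mask path.
#' @param volume the paired \code{mri_volume}.
#' @return An \code{mri_mask}.
#' @export
read_nifti_mask <- function(path, volume) {
  m <- read_nifti_volume(path)
  if (!identical(dim(m$data), dim(volume$data)))
    stop("mask grid does not match the paired volume")
  if (max(abs(m$spacing - volume$spacing)) > 1e-4)
    stop("mask voxel spacing does not match the paired volume")
  mri_mask(m$data != 0, volume)
}

#' Load a volume from NIfTI or a DICOM series
#'
#' Dispatches on \code{format}; \code{"auto"} treats a directory as a DICOM
#' series and a file as NIfTI.
#'
#' @param path NIfTI file or DICOM series directory.
#' @param format \code{"auto"}, \code{"nifti"} or \code{"dicom"}.
#' @return An \code{mri_volume}.
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  switch(format,
         nifti = read_nifti_volume(path),
         dicom = read_dicom_series(path))
}
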