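## Minimal DICOM support: uncompressed, Explicit VR Little Endian,
## single-frame monochrome slices — the form in which scanner exports are
## consumed by this pipeline. The writer emits one file per axial slice
## with 16-bit pixels plus rescale slope/intercept; the reader parses any
## Explicit-VR-LE series with consistent orientation, ordering slices by
## the projection of ImagePositionPatient onto the slice normal (robust to
## renumbered InstanceNumbers).

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

uid_root <- "1.2.826.0.1.3680043.10.1567"  # arbitrary org root for generated UIDs

dcm_pad <- function(raw_val) {
  if (length(raw_val) %% 2L == 1L) c(raw_val, as.raw(0L)) else raw_val
}

dcm_str <- function(s, ui = FALSE) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L)
    r <- c(r, if (ui) as.raw(0L) else charToRaw(" "))  # UI pads with NUL
  r
}

## one explicit-VR element as raw bytes
dcm_element <- function(group, element, vr, value_raw) {
  head <- writeBin(as.integer(c(group, element)), raw(), size = 2L,
                   endian = "little")
  value_raw <- dcm_pad(value_raw)
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, charToRaw(vr), as.raw(c(0L, 0L)),
      writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
      value_raw)
  } else {
    c(head, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2L, endian = "little"),
      value_raw)
  }
}

dcm_ds <- function(...) {
  paste(vapply(list(...), function(x) sprintf("%.10g", x), ""), collapse = "\\")
}

#' Write a volume as a DICOM series
#'
#' One Explicit-VR little-endian file per axial slice, 16-bit monochrome
#' with rescale slope/intercept so floating-point intensities survive to
#' about 1 part in 65535 of the volume maximum. Intended for round-trip
#' interchange with the reader and with standard DICOM tooling.
#'
#' @param volume an \code{mri_volume}.
#' @param dir output directory (created if needed).
#' @param instance_numbers optional integer vector of InstanceNumber values
#'   (default 1..n; permuting them must not affect reloading order).
#' @param z_positions optional per-slice world z positions (mm) written to
#'   ImagePositionPatient; defaults to the volume's regular grid.
#' @return The directory path, invisibly.
#' @export
write_dicom_series <- function(volume, dir, instance_numbers = NULL,
                               z_positions = NULL) {
  if (!inherits(volume, "mri_volume")) stop("'volume' must be an mri_volume")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$data)
  if (is.null(instance_numbers)) instance_numbers <- seq_len(d[3L])
  if (is.null(z_positions)) z_positions <- axis_coords(volume, 3L)
  vmax <- max(volume$data)
  slope <- if (vmax > 0) vmax / 65535 else 1
  series_uid <- paste0(uid_root, ".", format(Sys.time(), "%Y%m%d%H%M%S"), ".",
                       sample.int(1e6, 1L))
  for (k in seq_len(d[3L])) {
    sl <- volume$data[, , k]
    pix <- as.integer(round(sl / slope))
    pix_raw <- writeBin(pix, raw(), size = 2L, endian = "little")
    sop_uid <- paste0(series_uid, ".", k)
    meta <- c(
      dcm_element(0x0002, 0x0002, "UI", dcm_str("1.2.840.10008.5.1.4.1.1.4", ui = TRUE)),
      dcm_element(0x0002, 0x0003, "UI", dcm_str(sop_uid, ui = TRUE)),
      dcm_element(0x0002, 0x0010, "UI", dcm_str(TRANSFER_SYNTAX_EXPLICIT_LE, ui = TRUE)))
    meta <- c(dcm_element(0x0002, 0x0000, "UL",
                          writeBin(length(meta), raw(), size = 4L,
                                   endian = "little")),
              meta)
    body <- c(
      dcm_element(0x0008, 0x0016, "UI", dcm_str("1.2.840.10008.5.1.4.1.1.4", ui = TRUE)),
      dcm_element(0x0008, 0x0018, "UI", dcm_str(sop_uid, ui = TRUE)),
      dcm_element(0x0008, 0x0060, "CS", dcm_str("MR")),
      dcm_element(0x0018, 0x0050, "DS", dcm_str(dcm_ds(volume$spacing[3L]))),
      dcm_element(0x0020, 0x000E, "UI", dcm_str(series_uid, ui = TRUE)),
      dcm_element(0x0020, 0x0013, "IS", dcm_str(sprintf("%d", instance_numbers[k]))),
      dcm_element(0x0020, 0x0032, "DS",
                  dcm_str(dcm_ds(volume$origin[1L], volume$origin[2L],
                                 z_positions[k]))),
      dcm_element(0x0020, 0x0037, "DS", dcm_str("1\\0\\0\\0\\1\\0")),
      dcm_element(0x0028, 0x0002, "US", writeBin(1L, raw(), size = 2L,
                                                 endian = "little")),
      dcm_element(0x0028, 0x0004, "CS", dcm_str("MONOCHROME2")),
      dcm_element(0x0028, 0x0010, "US", writeBin(d[2L], raw(), size = 2L,
                                                 endian = "little")),
      dcm_element(0x0028, 0x0011, "US", writeBin(d[1L], raw(), size = 2L,
                                                 endian = "little")),
      dcm_element(0x0028, 0x0030, "DS",
                  dcm_str(dcm_ds(volume$spacing[2L], volume$spacing[1L]))),
      dcm_element(0x0028, 0x0100, "US", writeBin(16L, raw(), size = 2L,
                                                 endian = "little")),
      dcm_element(0x0028, 0x0101, "US", writeBin(16L, raw(), size = 2L,
                                                 endian = "little")),
      dcm_element(0x0028, 0x0102, "US", writeBin(15L, raw(), size = 2L,
                                                 endian = "little")),
      dcm_element(0x0028, 0x0103, "US", writeBin(0L, raw(), size = 2L,
                                                 endian = "little")),
      dcm_element(0x0028, 0x1052, "DS", dcm_str(dcm_ds(0))),
      dcm_element(0x0028, 0x1053, "DS", dcm_str(dcm_ds(slope))),
      dcm_element(0x7FE0, 0x0010, "OW", pix_raw))
    con <- file(file.path(dir, sprintf("slice_%03d.dcm", k)), "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(dir)
}

## parse one Explicit-VR-LE DICOM file into a named list of the tags the
## pipeline needs
parse_dicom_file <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 140L ||
      !identical(rawToChar(bytes[129:132]), "DICM"))
    stop("not a DICOM (part-10) file: ", path)
  pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  read_u16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2L,
                                   signed = FALSE, endian = "little")
  read_u32 <- function(at) readBin(bytes[at:(at + 3L)], "integer", size = 4L,
                                   endian = "little")
  while (pos + 7L <= length(bytes)) {
    group <- read_u16(pos); element <- read_u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- read_u32(pos + 8L)
      val_at <- pos + 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- read_u16(pos + 6L)
      val_at <- pos + 8L
    } else {
      stop(sprintf("unsupported (implicit-VR?) encoding at tag (%04X,%04X) in %s",
                   group, element, path))
    }
    if (len < 0 || val_at + len - 1L > length(bytes))
      stop("truncated DICOM element in ", path)
    key <- sprintf("%04X%04X", group, element)
    val <- bytes[val_at:(val_at + len - 1L)]
    if (len == 0L) val <- raw(0L)
    tags[[key]] <- list(vr = vr, value = val)
    pos <- val_at + len
    if (group == 0x7FE0 && element == 0x0010) break
  }
  tags
}

tag_string <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  v <- t$value
  while (length(v) > 0L && v[length(v)] %in% as.raw(c(0L, 32L)))
    v <- v[-length(v)]
  rawToChar(v)
}

tag_numbers <- function(tags, key) {
  s <- tag_string(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1L]])
}

tag_u16 <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$value, "integer", size = 2L, signed = FALSE, endian = "little")
}

#' Read a DICOM series as a volume
#'
#' Reads every \code{.dcm}/\code{.ima}/extension-less DICOM file in a
#' directory, orders slices by the projection of ImagePositionPatient onto
#' the slice normal (never by file name or InstanceNumber), applies the
#' rescale slope/intercept, and validates geometry: one shared orientation
#' and in-plane spacing, and uniform inter-slice spacing to within 1%.
#'
#' @param dir directory containing one DICOM series.
#' @return An \code{mri_volume} with spacing from PixelSpacing and the
#'   measured inter-slice distance.
#' @export
read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop("DICOM directory not found: ", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  files <- files[grepl("\\.(dcm|ima)$", files, ignore.case = TRUE) |
                 !grepl("\\.", basename(files))]
  if (length(files) == 0L) stop("no DICOM files in ", dir)
  slices <- lapply(files, parse_dicom_file)

  iop <- tag_numbers(slices[[1L]], "00200037")
  if (is.null(iop) || length(iop) != 6L)
    stop("missing ImageOrientationPatient in ", files[1L])
  pix_sp <- tag_numbers(slices[[1L]], "00280030")
  if (is.null(pix_sp) || length(pix_sp) != 2L || any(pix_sp <= 0))
    stop("missing PixelSpacing metadata in ", files[1L])
  for (i in seq_along(slices)) {
    iop_i <- tag_numbers(slices[[i]], "00200037")
    if (is.null(iop_i) || max(abs(iop_i - iop)) > 1e-4)
      stop("inconsistent slice orientation in ", files[i])
    sp_i <- tag_numbers(slices[[i]], "00280030")
    if (is.null(sp_i) || max(abs(sp_i - pix_sp)) > 1e-6)
      stop("inconsistent in-plane pixel spacing in ", files[i])
  }
  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- c(row_dir[2L] * col_dir[3L] - row_dir[3L] * col_dir[2L],
              row_dir[3L] * col_dir[1L] - row_dir[1L] * col_dir[3L],
              row_dir[1L] * col_dir[2L] - row_dir[2L] * col_dir[1L])
  ipp <- lapply(slices, tag_numbers, "00200032")
  if (any(vapply(ipp, is.null, TRUE)))
    stop("missing ImagePositionPatient in series ", dir)
  proj <- vapply(ipp, function(p) sum(p * normal), 0)
  ord <- order(proj)
  slices <- slices[ord]; files <- files[ord]; proj <- proj[ord]; ipp <- ipp[ord]

  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(proj)
    step <- stats::median(dz)
    if (step <= 0) stop("duplicate slice positions in ", dir)
    bad <- which(abs(dz - step) > 0.01 * step)
    if (length(bad) > 0L) {
      off <- unique(basename(files[c(bad, bad + 1L)]))
      stop("inconsistent inter-slice spacing (beyond 1%) at slices: ",
           paste(off, collapse = ", "))
    }
  } else {
    step <- tag_numbers(slices[[1L]], "00180050")
    if (is.null(step)) stop("single slice without SliceThickness in ", dir)
  }

  ncol_px <- tag_u16(slices[[1L]], "00280011")
  nrow_px <- tag_u16(slices[[1L]], "00280010")
  arr <- array(0, c(ncol_px, nrow_px, nz))
  for (k in seq_len(nz)) {
    t <- slices[[k]]
    px <- t[["7FE00010"]]
    if (is.null(px)) stop("missing pixel data in ", files[k])
    vals <- readBin(px$value, "integer", n = length(px$value) / 2L,
                    size = 2L, signed = FALSE, endian = "little")
    slope <- tag_numbers(t, "00281053"); icept <- tag_numbers(t, "00281052")
    if (is.null(slope)) slope <- 1
    if (is.null(icept)) icept <- 0
    arr[, , k] <- vals * slope + icept
  }
  ## PixelSpacing is (row spacing, column spacing) = (axis-2, axis-1)
  mri_volume(arr, spacing = c(pix_sp[2L], pix_sp[1L], step),
             origin = ipp[[1L]])
}
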