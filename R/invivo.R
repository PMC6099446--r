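#' Atelectasis reference intensity
#'
#' Mean muscle-normalized intensity of a cubic ROI placed in the middle of
#' non-aerated (atelectatic) lung tissue; this value anchors the
#' translation of ex vivo attenuation thresholds to the in vivo intensity
#' scale. If a lung mask is supplied the ROI must lie inside it. A warning
#' is raised when the ROI looks heterogeneous (coefficient of variation
#' above 10%), the signature of a cube spilling into aerated tissue.
#'
#' @param volume_normalized a muscle-normalized \code{mri_volume}.
#' @param roi an \code{roi_spec}, conventionally a 2.03 cm^3 cube.
#' @param mask optional \code{mri_mask}; every ROI voxel must be in it.
#' @return Scalar mean normalized intensity (MRI_ATEL).
#' @export
atelectasis_reference <- function(volume_normalized, roi, mask = NULL) {
  sel <- roi_voxels(volume_normalized, roi)
  if (sum(sel) == 0L) stop("ROI contains no voxel centres")
  if (!is.null(mask)) {
    stopifnot_same_grid(volume_normalized, mask)
    if (any(sel & !mask$data))
      stop("atelectasis ROI extends outside the lung mask")
  }
  vals <- volume_normalized$data[sel]
  m <- mean(vals)
  if (m > 0 && stats::sd(vals) / m > 0.10)
    warning(sprintf(
      "atelectasis ROI is heterogeneous (CV = %.0f%%); it may overlap aerated tissue",
      100 * stats::sd(vals) / m))
  m
}

#' Classify lung voxels into aeration compartments
#'
#' Applies intensity thresholds voxel-wise under the lung mask: intensity
#' at or above \code{t_nonaerated} is non-aerated, between \code{t_poor}
#' (inclusive) and \code{t_nonaerated} poorly aerated, below \code{t_poor}
#' normally or hyper-aerated (a single merged class). Thresholds must be
#' on the muscle-normalized intensity scale; attenuation-scale thresholds
#' must be translated first (see [translate_thresholds()]).
#'
#' @param volume_normalized muscle-normalized \code{mri_volume}.
#' @param mask lung \code{mri_mask}.
#' @param thresholds an \code{aeration_thresholds} on the
#'   \code{"muscle_normalized"} scale.
#' @param rounded use the two-decimal rounded thresholds instead of full
#'   precision.
#' @return An object of class \code{aeration_labels}: integer label array
#'   (0 outside mask, 1 non-aerated, 2 poorly aerated, 3 normally/hyper-
#'   aerated) plus geometry and the thresholds applied.
#' @export
classify_voxels <- function(volume_normalized, mask, thresholds,
                            rounded = FALSE) {
  if (!inherits(thresholds, "aeration_thresholds"))
    stop("'thresholds' must be an aeration_thresholds object")
  if (thresholds$scale != "muscle_normalized")
    stop("threshold scale mismatch: attenuation-scale thresholds cannot be ",
         "applied to an intensity volume; translate them first")
  stopifnot_same_grid(volume_normalized, mask)
  t_non <- if (rounded) thresholds$rounded[1L] else thresholds$t_nonaerated
  t_poor <- if (rounded) thresholds$rounded[2L] else thresholds$t_poor
  v <- volume_normalized$data
  lab <- array(0L, dim(v))
  lab[mask$data] <- ifelse(v[mask$data] >= t_non, 1L,
                           ifelse(v[mask$data] >= t_poor, 2L, 3L))
  structure(list(labels = lab, spacing = volume_normalized$spacing,
                 origin = volume_normalized$origin,
                 thresholds_applied = c(nonaerated = t_non, poor = t_poor),
                 rounded = rounded),
            class = "aeration_labels")
}

aeration_class_names <- c("nonaerated", "poorly_aerated", "normally_aerated")

#' Aeration compartment report
#'
#' Summarizes a classified scan into the standard quantitative readout:
#' total lung volume and, per compartment, absolute volume (mL) and
#' percentage of total lung volume; optionally the mean normalized signal
#' of the whole lung and of the ventral/dorsal halves.
#'
#' @param labels an \code{aeration_labels} from [classify_voxels()].
#' @param mask the lung \code{mri_mask} used for classification.
#' @param volume_normalized optional normalized \code{mri_volume} for the
#'   signal summaries.
#' @param scan_label optional label (e.g. \code{"pre"}, \code{"post"}).
#' @return An object of class \code{aeration_report}.
#' @export
compartment_report <- function(labels, mask, volume_normalized = NULL,
                               scan_label = NA_character_) {
  if (!inherits(labels, "aeration_labels"))
    stop("'labels' must come from classify_voxels()")
  vox_ml <- prod(labels$spacing) / 1000
  counts <- vapply(1:3, function(k) sum(labels$labels == k), 0)
  tlv <- sum(counts) * vox_ml
  vols <- counts * vox_ml
  pct <- if (tlv > 0) 100 * vols / tlv else rep(0, 3L)
  sig <- list(whole = NA_real_, ventral = NA_real_, dorsal = NA_real_)
  if (!is.null(volume_normalized)) {
    sig$whole <- mean_signal(volume_normalized, mask)
    halves <- ventro_dorsal_split(mask)
    sig$ventral <- mean_signal(volume_normalized, halves$ventral)
    sig$dorsal <- mean_signal(volume_normalized, halves$dorsal)
  }
  structure(
    list(scan_label = scan_label,
         total_lung_volume_ml = tlv,
         volume_ml = stats::setNames(vols, aeration_class_names),
         percent_of_tlv = stats::setNames(pct, aeration_class_names),
         mean_signal = sig,
         thresholds_applied = labels$thresholds_applied,
         rounded = labels$rounded),
    class = "aeration_report")
}

#' @export
print.aeration_report <- function(x, ...) {
  cat(sprintf("Aeration report%s\n",
              if (is.na(x$scan_label)) "" else sprintf(" [%s]", x$scan_label)))
  cat(sprintf("  total lung volume: %.0f mL\n", x$total_lung_volume_ml))
  lab <- c("non-aerated", "poorly aerated", "normally/hyper-aerated")
  for (k in 1:3)
    cat(sprintf("  %-22s %8.1f mL  (%5.1f%% of TLV)\n", lab[k],
                x$volume_ml[k], x$percent_of_tlv[k]))
  if (!is.na(x$mean_signal$whole))
    cat(sprintf("  normalized signal: whole %.3f, ventral %.3f, dorsal %.3f\n",
                x$mean_signal$whole, x$mean_signal$ventral,
                x$mean_signal$dorsal))
  cat(sprintf("  thresholds: %.4f / %.4f%s\n", x$thresholds_applied[1L],
              x$thresholds_applied[2L],
              if (isTRUE(x$rounded)) " (rounded)" else ""))
  invisible(x)
}

#' Flatten an aeration report to a one-row data.frame
#'
#' @param report an \code{aeration_report}.
#' @return data.frame with one row (scan label, TLV, per-class volumes and
#'   percentages, signal summaries, thresholds).
#' @export
report_as_row <- function(report) {
  data.frame(scan_label = report$scan_label,
             total_lung_volume_ml = report$total_lung_volume_ml,
             nonaerated_ml = report$volume_ml[["nonaerated"]],
             nonaerated_pct = report$percent_of_tlv[["nonaerated"]],
             poorly_aerated_ml = report$volume_ml[["poorly_aerated"]],
             poorly_aerated_pct = report$percent_of_tlv[["poorly_aerated"]],
             normally_aerated_ml = report$volume_ml[["normally_aerated"]],
             normally_aerated_pct = report$percent_of_tlv[["normally_aerated"]],
             signal_whole = report$mean_signal$whole,
             signal_ventral = report$mean_signal$ventral,
             signal_dorsal = report$mean_signal$dorsal,
             t_nonaerated = report$thresholds_applied[["nonaerated"]],
             t_poor = report$thresholds_applied[["poor"]])
}

#' Split a lung mask into ventral and dorsal halves
#'
#' Partitions the mask at the geometric midpoint of its bounding box along
#' the anterior-posterior axis (equal extent, not equal voxel count): the
#' two equally spaced ventro-dorsal ROIs of the regional analysis. Every
#' lung voxel lands in exactly one half.
#'
#' @param mask a non-empty \code{mri_mask}.
#' @return list with \code{ventral} and \code{dorsal} \code{mri_mask}.
#' @export
ventro_dorsal_split <- function(mask) {
  if (!inherits(mask, "mri_mask")) stop("'mask' must be an mri_mask")
  if (!any(mask$data)) stop("mask is empty")
  ap_axis <- which(mask$axes == "anterior-posterior")
  if (length(ap_axis) != 1L) stop("mask lacks an anterior-posterior axis label")
  idx <- which(mask$data, arr.ind = TRUE)[, ap_axis]
  y <- mask$origin[ap_axis] + (idx - 1) * mask$spacing[ap_axis]
  mid <- (min(y) + max(y)) / 2
  coord <- axis_coords(mask, ap_axis)
  ventral_plane <- coord < mid
  keep <- array(FALSE, dim(mask$data))
  if (ap_axis == 2L) {
    keep <- aperm(array(ventral_plane,
                        dim(mask$data)[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
  } else {
    stop("unsupported axis ordering")  # fixed convention: AP is axis 2
  }
  list(ventral = mri_mask(mask$data & keep, mask),
       dorsal = mri_mask(mask$data & !keep, mask))
}

#' Sensitivity of compartment sizes to threshold perturbation
#'
#' Recomputes the compartment report with each threshold scaled by
#' (1 - p) and (1 + p), separately and jointly, and tabulates the change
#' in each compartment's share of total lung volume — the robustness check
#' for threshold uncertainty.
#'
#' @param volume_normalized muscle-normalized \code{mri_volume}.
#' @param mask lung \code{mri_mask}.
#' @param thresholds \code{aeration_thresholds} (muscle-normalized scale).
#' @param perturbation relative perturbation, default 0.05 (±5%).
#' @return data.frame with one row per scenario: scenario name, perturbed
#'   thresholds, and signed deltas of each class in percent of TLV;
#'   attribute \code{"max_abs_delta"} carries the largest absolute delta.
#' @export
threshold_sensitivity <- function(volume_normalized, mask, thresholds,
                                  perturbation = 0.05) {
  base <- compartment_report(
    classify_voxels(volume_normalized, mask, thresholds), mask)
  scen <- list(
    nonaerated_down = c(1 - perturbation, 1),
    nonaerated_up = c(1 + perturbation, 1),
    poor_down = c(1, 1 - perturbation),
    poor_up = c(1, 1 + perturbation),
    both_down = c(1 - perturbation, 1 - perturbation),
    both_up = c(1 + perturbation, 1 + perturbation))
  rows <- lapply(names(scen), function(nm) {
    f <- scen[[nm]]
    th <- threshold_set(thresholds$t_nonaerated * f[1L],
                        thresholds$t_poor * f[2L])
    rep_p <- compartment_report(classify_voxels(volume_normalized, mask, th),
                                mask)
    d <- rep_p$percent_of_tlv - base$percent_of_tlv
    data.frame(scenario = nm,
               t_nonaerated = th$t_nonaerated, t_poor = th$t_poor,
               delta_nonaerated_pct = d[["nonaerated"]],
               delta_poor_pct = d[["poorly_aerated"]],
               delta_normal_pct = d[["normally_aerated"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "max_abs_delta") <- max(abs(as.matrix(out[, 4:6])))
  out
}
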