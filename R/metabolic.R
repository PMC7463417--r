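# Traditional semiquantitative PET metrics: SUVmax, metabolic tumor
# volume (MTV) at a fractional threshold, manual-ROI volume, and maximal
# diameter.

#' Maximum intensity within the ROI
#'
#' With intensities in standardized-uptake-value units this is the SUVmax;
#' the package treats the units as opaque.
#'
#' @param volume An [image_volume()].
#' @param mask A nonempty congruent [roi_mask()].
#' @return Scalar maximum masked intensity.
#' @export
suv_max <- function(volume, mask) {
  max(masked_values(volume, mask))
}

#' Metabolic tumor volume
#'
#' Volume of the masked voxels whose intensity is strictly higher than
#' `fraction` times the ROI maximum ("higher than the threshold of
#' 41% x SUVmax"); ties at exactly the threshold are excluded. The
#' threshold is applied within the supplied ROI rather than within an
#' operator-drawn cropping sphere: the sphere is an interactive artifact
#' of the clinical workstation and is not reproducible.
#'
#' @param volume An [image_volume()].
#' @param mask A nonempty congruent [roi_mask()].
#' @param fraction Threshold fraction of the maximum, in (0, 1);
#'   default 0.41.
#' @return MTV in mm^3.
#' @export
metabolic_tumor_volume <- function(volume, mask, fraction = 0.41) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    pettex_error("'fraction' must lie strictly between 0 and 1",
                 "pettex_domain_error")
  }
  v <- masked_values(volume, mask)
  sum(v > fraction * max(v)) * voxel_volume_mm3(volume)
}

#' ROI volume
#'
#' Voxel count of the (manually drawn) ROI times the voxel volume.
#'
#' @param mask A nonempty [roi_mask()].
#' @return Volume in mm^3.
#' @export
roi_volume <- function(mask) {
  check_nonempty(mask)
  sum(mask$flags) * voxel_volume_mm3(mask)
}

#' Maximal diameter of the ROI
#'
#' Maximum Euclidean distance between the centers of any two masked
#' voxels, in mm. For a single-slice mask this is the in-plane maximal
#' diameter. The exhaustive all-pairs search is pruned to the surface
#' voxels of the mask, which always contain both endpoints of a diameter.
#'
#' @param mask A nonempty [roi_mask()].
#' @return Length in mm (0 for a single voxel).
#' @export
max_diameter <- function(mask) {
  check_nonempty(mask)
  m <- mask$flags
  surf <- m & !(
    shift_logical(m, 1, 0, 0) & shift_logical(m, -1, 0, 0) &
    shift_logical(m, 0, 1, 0) & shift_logical(m, 0, -1, 0) &
    shift_logical(m, 0, 0, 1) & shift_logical(m, 0, 0, -1))
  pts <- masked_coordinates_mm(roi_mask(surf, mask$spacing_mm))
  n <- nrow(pts)
  if (n == 1L) return(0)
  best <- 0
  for (i in seq_len(n - 1L)) {
    d2 <- (pts[(i + 1L):n, 1] - pts[i, 1])^2 +
      (pts[(i + 1L):n, 2] - pts[i, 2])^2 +
      (pts[(i + 1L):n, 3] - pts[i, 3])^2
    best <- max(best, d2)
  }
  sqrt(best)
}

#' All semiquantitative metrics for one volume/mask pair
#'
#' @inheritParams metabolic_tumor_volume
#' @return Named numeric vector: `suvmax`, `mtv_mm3`, `volume_mm3`,
#'   `max_diameter_mm`.
#' @export
metabolic_metrics <- function(volume, mask, fraction = 0.41) {
  c(suvmax = suv_max(volume, mask),
    mtv_mm3 = metabolic_tumor_volume(volume, mask, fraction),
    volume_mm3 = roi_volume(mask),
    max_diameter_mm = max_diameter(mask))
}
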