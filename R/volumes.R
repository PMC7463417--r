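# Core containers: gridded image volumes and binary ROI masks.
#
# Axis convention throughout the package: arrays are indexed (z, y, x),
# 0 voxels of padding assumed, spacings are mm per axis in the same order.
# A single CT slice is stored as a 3-D volume with z-extent 1 so that the
# 2-D and 3-D feature paths share one code path.

pettex_error <- function(message, class) {
  stop(errorCondition(message, class = c(class, "pettex_error", "error")))
}

#' Construct an image volume
#'
#' A 3-D grid of finite intensities (grey-level units, treated as opaque)
#' with physical voxel spacing. The array is indexed `(z, y, x)`.
#'
#' @param values Numeric 3-D array of finite values.
#' @param spacing_mm Positive numeric vector of length 3: voxel spacing in
#'   mm along `(z, y, x)`.
#' @return An object of class `image_volume` with elements `values` and
#'   `spacing_mm`.
#' @examples
#' vol <- image_volume(array(1, c(4, 4, 4)), c(4, 4, 4))
#' dim(vol$values)
#' @export
image_volume <- function(values, spacing_mm = c(4, 4, 4)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    pettex_error("'values' must be a 3-D array", "pettex_domain_error")
  }
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) {
    pettex_error("image volume contains non-finite values",
                 "pettex_domain_error")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    pettex_error("'spacing_mm' must be 3 positive finite values",
                 "pettex_domain_error")
  }
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "image_volume")
}

#' Construct a binary ROI mask
#'
#' A logical grid congruent with its image volume. Single-slice (CT) masks
#' have z-extent 1.
#'
#' @param flags Logical (or 0/1 numeric) 3-D array.
#' @param spacing_mm Voxel spacing in mm along `(z, y, x)`.
#' @return An object of class `roi_mask` with elements `flags` and
#'   `spacing_mm`.
#' @export
roi_mask <- function(flags, spacing_mm = c(4, 4, 4)) {
  if (!is.array(flags) || length(dim(flags)) != 3L) {
    pettex_error("'flags' must be a 3-D array", "pettex_domain_error")
  }
  if (is.numeric(flags)) {
    if (any(!flags %in% c(0, 1))) {
      pettex_error("mask values must be 0/1 or logical",
                   "pettex_domain_error")
    }
    flags <- array(flags == 1, dim(flags))
  }
  if (!is.logical(flags) || anyNA(flags)) {
    pettex_error("mask must be logical without missing values",
                 "pettex_domain_error")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    pettex_error("'spacing_mm' must be 3 positive finite values",
                 "pettex_domain_error")
  }
  structure(list(flags = flags, spacing_mm = spacing_mm),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing (z,y,x) =",
      paste(format(x$spacing_mm), collapse = " x "), "mm\n")
  cat("  intensity range:", format(range(x$values)), "\n")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("roi_mask:", paste(dim(x$flags), collapse = " x "),
      "voxels,", sum(x$flags), "set\n")
  invisible(x)
}

voxel_volume_mm3 <- function(x) prod(x$spacing_mm)

# Geometry contract: mask must be congruent with the volume (identical grid
# and spacing). No implicit resampling, ever -- resampling corrupts the
# texture statistics.
check_congruent <- function(volume, mask, what = "mask") {
  if (!identical(dim(volume$values), dim(mask$flags))) {
    pettex_error(
      sprintf("%s shape (%s) does not match volume shape (%s)",
              what, paste(dim(mask$flags), collapse = "x"),
              paste(dim(volume$values), collapse = "x")),
      "pettex_geometry_error")
  }
  if (max(abs(volume$spacing_mm - mask$spacing_mm)) > 1e-6) {
    pettex_error(sprintf("%s spacing does not match volume spacing", what),
                 "pettex_geometry_error")
  }
  invisible(TRUE)
}

check_nonempty <- function(mask) {
  if (!any(mask$flags)) {
    pettex_error("mask is empty", "pettex_domain_error")
  }
  invisible(TRUE)
}

#' Extract masked intensities
#'
#' @param volume An [image_volume()].
#' @param mask A congruent [roi_mask()].
#' @return Numeric vector of intensities at masked voxels.
#' @export
masked_values <- function(volume, mask) {
  check_congruent(volume, mask)
  check_nonempty(mask)
  volume$values[mask$flags]
}

# Physical coordinates (mm) of the centers of the masked voxels, n x 3,
# columns (z, y, x). 0-based indices times spacing.
masked_coordinates_mm <- function(mask) {
  idx <- which(mask$flags, arr.ind = TRUE)
  sweep(idx - 1, 2, mask$spacing_mm, `*`)
}
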