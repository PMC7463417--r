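# Spherical-tumor PET phantoms with spatially correlated multiplicative
# heterogeneity. These stand in for the patient images, which are not
# publicly deposited; they reproduce the statistical structure the
# downstream analysis assumes (hotter / larger / more heterogeneous tumors
# in the non-responding group), not anatomy.

#' Specify a phantom
#'
#' Describes a synthetic PET volume containing a single spherical tumor on
#' a uniform background. Heterogeneity is log-normal multiplicative noise:
#' a white Gaussian field smoothed with a Gaussian kernel of width
#' `correlation_length_mm`, standardized to `heterogeneity_sd` on the log
#' scale, and exponentiated. This single knob moves both the first-order
#' entropy and the co-occurrence features in the direction seen in
#' heterogeneous tumors.
#'
#' @param grid_shape Integer voxel counts per axis `(z, y, x)`.
#' @param voxel_spacing_mm Positive spacing per axis, mm. The default
#'   4 x 4 x 4 mm matches a typical clinical PET reconstruction.
#' @param tumor_radius_mm Sphere radius, mm; must fit inside the grid.
#' @param base_intensity Tumor grey level (arbitrary units, > 0).
#' @param heterogeneity_sd Standard deviation of the log-intensity field
#'   (>= 0; 0 gives a perfectly uniform tumor).
#' @param correlation_length_mm Gaussian smoothing width of the noise
#'   field, mm (0 = white noise).
#' @param background_intensity Background grey level, in \[0,
#'   `base_intensity`).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(36, 36, 36),
                         voxel_spacing_mm = c(4, 4, 4),
                         tumor_radius_mm = 21.5,
                         base_intensity = 4000,
                         heterogeneity_sd = 0.25,
                         correlation_length_mm = 6,
                         background_intensity = 400) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 3L))
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0)) {
    pettex_error("voxel spacings must be positive", "pettex_domain_error")
  }
  if (tumor_radius_mm <= 0) {
    pettex_error("tumor radius must be positive", "pettex_domain_error")
  }
  max_radius <- min((grid_shape - 1) / 2 * voxel_spacing_mm)
  if (tumor_radius_mm > max_radius) {
    pettex_error(sprintf(
      "tumor radius %.1f mm does not fit: grid supports at most %.1f mm",
      tumor_radius_mm, max_radius), "pettex_geometry_error")
  }
  if (base_intensity <= 0 || background_intensity < 0 ||
      background_intensity >= base_intensity) {
    pettex_error(
      "need base_intensity > background_intensity >= 0",
      "pettex_domain_error")
  }
  if (heterogeneity_sd < 0 || correlation_length_mm < 0) {
    pettex_error("noise parameters must be nonnegative",
                 "pettex_domain_error")
  }
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = voxel_spacing_mm,
                 tumor_radius_mm = tumor_radius_mm,
                 base_intensity = base_intensity,
                 heterogeneity_sd = heterogeneity_sd,
                 correlation_length_mm = correlation_length_mm,
                 background_intensity = background_intensity),
            class = "phantom_spec")
}

# Row-normalized Gaussian smoothing matrix for one axis; exact mass
# preservation at the edges.
gaussian_axis_kernel <- function(n, spacing, corr_len) {
  pos <- (seq_len(n) - 1) * spacing
  K <- outer(pos, pos, function(a, b) exp(-(a - b)^2 / (2 * corr_len^2)))
  K / rowSums(K)
}

smooth_field <- function(field, spacing, corr_len) {
  if (corr_len <= 0) return(field)
  d <- dim(field)
  k1 <- gaussian_axis_kernel(d[1], spacing[1], corr_len)
  field <- array(k1 %*% matrix(field, d[1]), d)
  k2 <- gaussian_axis_kernel(d[2], spacing[2], corr_len)
  field <- aperm(array(k2 %*% matrix(aperm(field, c(2, 1, 3)), d[2]),
                       d[c(2, 1, 3)]), c(2, 1, 3))
  k3 <- gaussian_axis_kernel(d[3], spacing[3], corr_len)
  field <- aperm(array(k3 %*% matrix(aperm(field, c(3, 1, 2)), d[3]),
                       d[c(3, 1, 2)]), c(2, 3, 1))
  field
}

# Run `expr` under a private RNG stream, restoring the caller's state.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a phantom volume and tumor mask
#'
#' Deterministic in `(spec, seed)`: identical inputs reproduce bit-identical
#' output. The tumor mask is the set of voxel centers inside the sphere;
#' intensities are `level * exp(field)` where `level` is the tumor or
#' background grey level and `field` is the standardized correlated
#' Gaussian log-noise (identically zero when `heterogeneity_sd = 0`).
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the phantom's private RNG stream.
#' @return List with elements `volume` ([image_volume()]) and `mask`
#'   ([roi_mask()]).
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 16),
#'                                     tumor_radius_mm = 12), seed = 1)
#' sum(ph$mask$flags)
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  center <- (d + 1) / 2
  ax <- lapply(1:3, function(k) ((seq_len(d[k]) - center[k]) * sp[k])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  inside <- array(r2 <= spec$tumor_radius_mm^2, d)
  if (!any(inside)) {
    pettex_error("tumor sphere contains no voxel centers",
                 "pettex_geometry_error")
  }
  level <- ifelse(inside, spec$base_intensity, spec$background_intensity)
  values <- with_private_seed(seed, {
    if (spec$heterogeneity_sd > 0) {
      field <- array(stats::rnorm(prod(d)), d)
      field <- smooth_field(field, sp, spec$correlation_length_mm)
      field <- field / stats::sd(field) * spec$heterogeneity_sd
      level * exp(field)
    } else {
      level
    }
  })
  list(volume = image_volume(array(values, d), sp),
       mask = roi_mask(inside, sp))
}
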