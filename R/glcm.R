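# Grey-level co-occurrence matrices and the four derived statistics.
#
# Co-occurrences are accumulated per axial slice (matching slice-by-slice
# ROI drawing; the CT case is a single slice) for one of four in-plane
# directions at a fixed voxel distance. Both voxels of a pair must lie
# inside the mask.

GLCM_DIRECTIONS <- list(`10` = c(0L, 1L),   # 0 degrees   (row, col)
                        `11` = c(1L, 1L),   # 45 degrees
                        `12` = c(1L, 0L),   # 90 degrees
                        `13` = c(1L, -1L))  # 135 degrees

#' Specify a co-occurrence matrix
#'
#' Direction labels 10--13 denote the four distance-`distance` in-plane
#' offsets 0, 45, 90 and 135 degrees, i.e. `(0,1)`, `(1,1)`, `(1,0)` and
#' `(1,-1)` in (row, column) steps.
#'
#' @param distance Positive integer offset length in voxels (default 1).
#' @param direction One of 10, 11, 12, 13.
#' @param symmetric Count each ordered pair in both orders (default
#'   `TRUE`), making the matrix symmetric.
#' @return An object of class `glcm_spec`.
#' @export
glcm_spec <- function(distance = 1L, direction = 10L, symmetric = TRUE) {
  distance <- as.integer(distance)
  if (is.na(distance) || distance < 1L) {
    pettex_error("'distance' must be a positive integer",
                 "pettex_domain_error")
  }
  direction <- as.character(direction)
  if (!direction %in% names(GLCM_DIRECTIONS)) {
    pettex_error("'direction' must be one of 10, 11, 12, 13",
                 "pettex_domain_error")
  }
  structure(list(distance = distance, direction = direction,
                 offset = GLCM_DIRECTIONS[[direction]] * distance,
                 symmetric = isTRUE(symmetric)),
            class = "glcm_spec")
}

#' Grey-level co-occurrence matrix of a masked image
#'
#' Intensities are discretized over the whole ROI (all slices) with
#' `disc`, then co-occurrence counts are accumulated per axial slice for
#' the offset in `spec`, symmetrized when requested, and normalized to
#' sum 1.
#'
#' @param image An [image_volume()] (z-extent 1 for a CT slice).
#' @param mask A nonempty congruent [roi_mask()].
#' @param spec A [glcm_spec()].
#' @param disc A [discretization_spec()].
#' @return Object of class `glcm_matrix`: list with the normalized matrix
#'   `P` (`n_bins` x `n_bins`), the pair count `n_pairs`, and `spec`.
#' @export
glcm_matrix <- function(image, mask, spec = glcm_spec(),
                        disc = discretization_spec()) {
  check_congruent(image, mask)
  check_nonempty(mask)
  k <- disc$n_bins
  q <- array(NA_integer_, dim(image$values))
  q[mask$flags] <- discretize_levels(image$values[mask$flags], disc)
  d <- dim(q)
  dr <- spec$offset[1]; dc <- spec$offset[2]
  rows_a <- seq_len(d[2] - abs(dr)); rows_b <- rows_a + abs(dr)
  if (dr < 0) { tmp <- rows_a; rows_a <- rows_b; rows_b <- tmp }
  if (dc >= 0) {
    cols_a <- seq_len(d[3] - dc); cols_b <- cols_a + dc
  } else {
    cols_b <- seq_len(d[3] + dc); cols_a <- cols_b - dc
  }
  if (length(rows_a) == 0L || length(cols_a) == 0L) {
    pettex_error(sprintf("no voxel pairs for GLCM direction %s",
                         spec$direction), "pettex_domain_error")
  }
  a <- q[, rows_a, cols_a, drop = FALSE]
  b <- q[, rows_b, cols_b, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    pettex_error(sprintf(
      "mask has no valid voxel pair for GLCM direction %s",
      spec$direction), "pettex_domain_error")
  }
  counts <- matrix(tabulate(a[ok] + (b[ok] - 1L) * k, k * k), k, k)
  if (spec$symmetric) counts <- counts + t(counts)
  structure(list(P = counts / sum(counts), n_pairs = sum(ok), spec = spec),
            class = "glcm_matrix")
}

#' @export
print.glcm_matrix <- function(x, ...) {
  occ <- which(x$P > 0, arr.ind = TRUE)
  cat(sprintf(
    "glcm_matrix: direction %s, distance %d, %d pairs, %d occupied cells\n",
    x$spec$direction, x$spec$distance, x$n_pairs, nrow(occ)))
  invisible(x)
}

#' Texture statistics of a co-occurrence matrix
#'
#' For the normalized matrix \eqn{P(i,j)}:
#' energy \eqn{\sum_i\sum_j P^2(i,j)} (uniformity of grey-level pairs),
#' entropy \eqn{-\sum\sum P \log_2 P} (disorder, with \eqn{0\log 0 = 0}),
#' inertia \eqn{\sum\sum (i-j)^2 P} (contrast / local variation), and
#' variance \eqn{\sum\sum (i-\mu)^2 P} with \eqn{\mu = \sum\sum i\,P}
#' (dispersion of grey levels about their co-occurrence mean).
#'
#' @param P A [glcm_matrix()] or a normalized square matrix.
#' @return Named numeric vector: `entropy_glcm`, `energy_glcm`,
#'   `inertia_glcm`, `variance_glcm`.
#' @export
glcm_features <- function(P) {
  if (inherits(P, "glcm_matrix")) P <- P$P
  if (!is.matrix(P) || nrow(P) != ncol(P) || any(P < 0)) {
    pettex_error("P must be a square nonnegative matrix",
                 "pettex_domain_error")
  }
  if (abs(sum(P) - 1) > 1e-8) {
    pettex_error("P must be normalized to sum 1", "pettex_domain_error")
  }
  k <- nrow(P)
  i <- matrix(seq_len(k), k, k)
  j <- t(i)
  mu <- sum(i * P)
  c(entropy_glcm = shannon_entropy(as.vector(P)),
    energy_glcm = sum(P^2),
    inertia_glcm = sum((i - j)^2 * P),
    variance_glcm = sum((i - mu)^2 * P))
}
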