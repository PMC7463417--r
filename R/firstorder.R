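# First-order (histogram) features of the ROI intensity distribution.

#' Discretization settings for histogram and co-occurrence features
#'
#' Grey levels are binned into `n_bins` equal-width bins over the ROI's
#' own min--max range (`"roi-min-max"`, the common radiomics default) or a
#' fixed range. The mode and max-frequency are computed on
#' integer-quantized intensities (counts of the most frequent integer
#' grey level), independent of the binning.
#'
#' @param n_bins Number of bins (>= 2); default 256.
#' @param range_policy `"roi-min-max"` or `"fixed"`.
#' @param fixed_range Length-2 numeric range, required when
#'   `range_policy = "fixed"`.
#' @param integer_quantize_for_mode Round intensities to integers before
#'   computing mode/max-frequency (default `TRUE`).
#' @return An object of class `discretization_spec`.
#' @export
discretization_spec <- function(n_bins = 256L,
                                range_policy = c("roi-min-max", "fixed"),
                                fixed_range = NULL,
                                integer_quantize_for_mode = TRUE) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) {
    pettex_error("'n_bins' must be an integer >= 2", "pettex_domain_error")
  }
  range_policy <- match.arg(range_policy)
  if (range_policy == "fixed" &&
      (length(fixed_range) != 2L || diff(fixed_range) <= 0)) {
    pettex_error("fixed range policy needs an increasing length-2 range",
                 "pettex_domain_error")
  }
  structure(list(n_bins = n_bins, range_policy = range_policy,
                 fixed_range = fixed_range,
                 integer_quantize_for_mode = integer_quantize_for_mode),
            class = "discretization_spec")
}

# Bin assignment in 1..n_bins. A degenerate (zero-width) range maps all
# values to bin 1.
discretize_levels <- function(v, disc) {
  rng <- if (disc$range_policy == "fixed") disc$fixed_range else range(v)
  width <- diff(rng)
  if (width <= 0) return(rep(1L, length(v)))
  pmin(pmax(floor((v - rng[1]) / width * disc$n_bins) + 1L, 1L),
       disc$n_bins)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' First-order histogram features
#'
#' Computes the global intensity statistics of an ROI: mean, SD, minimum,
#' maximum and the cumulative 5/10/25/50/75/90th percentiles on the raw
#' values; mode and max-frequency (the count of the most frequent level,
#' ties broken toward the lowest grey level) on integer-quantized values;
#' skewness as the bias-uncorrected third standardized moment and kurtosis
#' as excess; and Shannon entropy (bits) of the `n_bins`-bin histogram
#' over the ROI range.
#'
#' @param values Numeric vector of masked intensities (length >= 1).
#' @param disc A [discretization_spec()].
#' @return Named numeric vector with components `mean`, `sd`,
#'   `max_frequency`, `mode`, `minimum`, `maximum`, `p5`, `p10`, `p25`,
#'   `p50`, `p75`, `p90`, `skewness`, `kurtosis`, `entropy`. Degenerate
#'   inputs (single value, zero variance) yield 0 for sd/skewness/kurtosis
#'   and carry a `"degenerate"` attribute.
#' @export
first_order_features <- function(values, disc = discretization_spec()) {
  if (length(values) < 1L || any(!is.finite(values))) {
    pettex_error("need at least one finite intensity",
                 "pettex_domain_error")
  }
  n <- length(values)
  m <- mean(values)
  degenerate <- FALSE
  if (n == 1L) {
    warning("single-voxel ROI: sd undefined, reported as 0")
    degenerate <- TRUE
    s <- 0
  } else {
    s <- stats::sd(values)
  }
  q <- stats::quantile(values, c(.05, .10, .25, .50, .75, .90),
                       names = FALSE, type = 7)
  m2 <- mean((values - m)^2)
  if (m2 > 0) {
    skew <- mean((values - m)^3) / m2^1.5
    kurt <- mean((values - m)^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0; degenerate <- TRUE
  }
  lv <- if (isTRUE(disc$integer_quantize_for_mode)) round(values) else values
  tab <- table(lv)
  max_freq <- max(tab)
  mode_level <- as.numeric(names(tab)[which.max(tab)])  # lowest wins ties
  counts <- tabulate(discretize_levels(values, disc), disc$n_bins)
  out <- c(mean = m, sd = s, max_frequency = as.numeric(max_freq),
           mode = mode_level, minimum = min(values), maximum = max(values),
           p5 = q[1], p10 = q[2], p25 = q[3], p50 = q[4], p75 = q[5],
           p90 = q[6], skewness = skew, kurtosis = kurt,
           entropy = shannon_entropy(counts / n))
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}
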