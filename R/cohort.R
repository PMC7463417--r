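# Two-group synthetic cohorts (CR vs non-CR). Effect multipliers >= 1 act
# on the non-CR group's tumor intensity, radius, and heterogeneity so that
# the non-responders are stochastically hotter, larger, and more
# heterogeneous; covariates are drawn from group-conditional distributions
# mirroring the published cohort's contingency structure.

#' Configure a synthetic cohort
#'
#' Defaults emulate the published 30-patient cohort: 20 complete responders
#' (CR) and 10 non-responders; non-CR tumors ~1.8x hotter, ~1.75x larger in
#' radius (~5.4x in volume), and 1.5x more heterogeneous; intestinal
#' involvement in 30% of CR vs 70% of non-CR patients; interim Deauville
#' scores drawn 3:8:9 over 1--3 for CR and 3:7 over 4--5 for non-CR. The
#' per-patient lognormal dispersions match the interquartile spreads of
#' the clinical feature table (intensity sdlog ~0.66, radius sdlog ~0.42,
#' i.e. volume sdlog ~1.25), so the group distributions overlap the way
#' the real cohort's do rather than separating perfectly.
#'
#' @param n_cr,n_noncr Group sizes (positive integers).
#' @param base_spec A [phantom_spec()] describing a CR-group tumor before
#'   per-patient variation.
#' @param intensity_multiplier,size_multiplier,heterogeneity_multiplier
#'   Non-CR effect multipliers, each >= 1 (1 = null configuration).
#' @param intensity_sdlog,radius_sdlog,heterogeneity_sdlog Log-scale SDs of
#'   per-patient lognormal variation around the group parameter.
#' @param p_intestinal Length-2 probability of intestinal involvement,
#'   `c(CR, nonCR)`.
#' @param p_stage 3 x 2 matrix of stage I/II/IV probabilities by group
#'   (columns CR, nonCR).
#' @param p_ipi_high Length-2 probability of IPI 3--5 by group.
#' @param p_ki67_high Length-2 probability of Ki67 >= 80% by group.
#' @param p_gcb Length-2 probability of the GCB subtype by group.
#' @param deauville_weights_cr Sampling weights for Deauville 1, 2, 3 in
#'   the CR group.
#' @param deauville_weights_noncr Weights for Deauville 4, 5 in non-CR.
#' @param reader2_perturbation Probability that each tumor surface voxel is
#'   eroded, and each adjacent background voxel dilated, in the synthetic
#'   second reader's mask.
#' @param ct_noise_sd SD of the additive noise on the attenuation-like CT
#'   slice.
#' @param seed Integer seed; the full cohort is a pure function of the
#'   config including the seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cr = 20L, n_noncr = 10L,
                          base_spec = phantom_spec(grid_shape = c(44, 44, 44)),
                          intensity_multiplier = 1.8,
                          size_multiplier = 1.75,
                          heterogeneity_multiplier = 1.5,
                          intensity_sdlog = 0.66,
                          radius_sdlog = 0.42,
                          heterogeneity_sdlog = 0.2,
                          p_intestinal = c(0.30, 0.70),
                          p_stage = cbind(cr = c(0.45, 0.275, 0.275),
                                          noncr = c(0.10, 0.40, 0.50)),
                          p_ipi_high = c(0.20, 0.50),
                          p_ki67_high = c(0.55, 0.70),
                          p_gcb = c(0.45, 0.40),
                          deauville_weights_cr = c(3, 8, 9),
                          deauville_weights_noncr = c(3, 7),
                          reader2_perturbation = 0.15,
                          ct_noise_sd = 3,
                          seed = 1L) {
  n_cr <- as.integer(n_cr); n_noncr <- as.integer(n_noncr)
  if (n_cr < 1L || n_noncr < 1L) {
    pettex_error("group sizes must be positive", "pettex_domain_error")
  }
  stopifnot(inherits(base_spec, "phantom_spec"))
  mult <- c(intensity_multiplier, size_multiplier, heterogeneity_multiplier)
  if (any(mult < 1)) {
    pettex_error(
      "effect multipliers must be >= 1 (non-CR dominates CR)",
      "pettex_domain_error")
  }
  probs <- c(p_intestinal, p_stage, p_ipi_high, p_ki67_high, p_gcb,
             reader2_perturbation)
  if (any(probs < 0 | probs > 1)) {
    pettex_error("probabilities must lie in [0,1]", "pettex_domain_error")
  }
  if (any(abs(colSums(p_stage) - 1) > 1e-8)) {
    pettex_error("stage probabilities must sum to 1 per group",
                 "pettex_domain_error")
  }
  structure(list(
    n_cr = n_cr, n_noncr = n_noncr, base_spec = base_spec,
    intensity_multiplier = intensity_multiplier,
    size_multiplier = size_multiplier,
    heterogeneity_multiplier = heterogeneity_multiplier,
    intensity_sdlog = intensity_sdlog, radius_sdlog = radius_sdlog,
    heterogeneity_sdlog = heterogeneity_sdlog,
    p_intestinal = p_intestinal, p_stage = unname(p_stage),
    p_ipi_high = p_ipi_high, p_ki67_high = p_ki67_high, p_gcb = p_gcb,
    deauville_weights_cr = deauville_weights_cr,
    deauville_weights_noncr = deauville_weights_noncr,
    reader2_perturbation = reader2_perturbation,
    ct_noise_sd = ct_noise_sd, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Read or write a cohort configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_cohort_config()` returns a [cohort_config()];
#'   `write_cohort_config()` invisibly returns `path`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec_args <- y$base_spec
  y$base_spec <- if (is.null(spec_args)) phantom_spec() else
    do.call(phantom_spec, spec_args)
  if (!is.null(y$p_stage)) y$p_stage <- matrix(unlist(y$p_stage), nrow = 3)
  do.call(cohort_config, y)
}

#' @rdname read_cohort_config
#' @param config A [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  y <- unclass(config)
  y$base_spec <- unclass(y$base_spec)
  y$p_stage <- list(cr = y$p_stage[, 1], noncr = y$p_stage[, 2])
  yaml::write_yaml(y, path)
  invisible(path)
}

# 6-neighbour shifts of a logical array (zero padding).
shift_logical <- function(m, dz, dy, dx) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  sh <- c(dz, dy, dx)
  for (k in 1:3) {
    if (abs(sh[k]) >= d[k]) return(out)
    if (sh[k] > 0) { dst[[k]] <- (1 + sh[k]):d[k]; src[[k]] <- 1:(d[k] - sh[k]) }
    if (sh[k] < 0) { dst[[k]] <- 1:(d[k] + sh[k]); src[[k]] <- (1 - sh[k]):d[k] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

neighbor_any <- function(m) {
  shift_logical(m, 1, 0, 0) | shift_logical(m, -1, 0, 0) |
    shift_logical(m, 0, 1, 0) | shift_logical(m, 0, -1, 0) |
    shift_logical(m, 0, 0, 1) | shift_logical(m, 0, 0, -1)
}

#' Perturb a mask boundary (synthetic second reader)
#'
#' Stochastic morphological perturbation: every tumor surface voxel is
#' independently eroded with probability `p`, and every background voxel
#' adjacent to the tumor is dilated into the mask with probability `p`.
#' This emulates interobserver contouring disagreement and yields
#' intraclass correlations below 1 without a second human reader. Interior
#' voxels are never touched, so the result is never empty for masks with
#' an interior.
#'
#' @param mask A [roi_mask()].
#' @param p Per-surface-voxel flip probability in \[0,1\].
#' @return A perturbed [roi_mask()].
#' @export
perturb_mask_boundary <- function(mask, p) {
  if (p < 0 || p > 1) {
    pettex_error("perturbation probability must be in [0,1]",
                 "pettex_domain_error")
  }
  m <- mask$flags
  touches_out <- m & !(
    shift_logical(m, 1, 0, 0) & shift_logical(m, -1, 0, 0) &
    shift_logical(m, 0, 1, 0) & shift_logical(m, 0, -1, 0) &
    shift_logical(m, 0, 0, 1) & shift_logical(m, 0, 0, -1))
  touches_in <- !m & neighbor_any(m)
  flip <- array(stats::runif(length(m)) < p, dim(m))
  out <- m
  out[touches_out & flip] <- FALSE
  out[touches_in & flip] <- TRUE
  if (!any(out)) out <- m  # degenerate tiny mask: keep reader 1's contour
  roi_mask(out, mask$spacing_mm)
}

# Attenuation-like CT slice: central PET slice rescaled to a soft-tissue
# window with independent additive noise. A plausible 2-D texture source,
# not a physical CT simulation.
make_ct_slice <- function(pet, pet_mask, noise_sd) {
  zc <- ceiling(dim(pet$values)[1] / 2)
  sl <- pet$values[zc, , , drop = FALSE]
  rng <- range(sl)
  span <- if (diff(rng) > 0) diff(rng) else 1
  ct <- 20 + 60 * (sl - rng[1]) / span +
    array(stats::rnorm(length(sl), sd = noise_sd), dim(sl))
  list(slice = image_volume(ct, pet$spacing_mm),
       mask = roi_mask(pet_mask$flags[zc, , , drop = FALSE],
                       pet_mask$spacing_mm))
}

#' Generate a synthetic two-group cohort
#'
#' Draws `n_cr + n_noncr` patients. Each patient gets a phantom PET volume
#' with per-patient lognormal variation of tumor intensity, radius, and
#' heterogeneity (non-CR parameters scaled by the effect multipliers), a
#' second-reader PET mask from [perturb_mask_boundary()], a CT slice with
#' its own pair of masks, group-conditional clinical covariates, and a
#' Deauville score consistent with the group label (CR draws from 1--3,
#' non-CR from 4--5). Pure function of the config, including its seed.
#'
#' @param config A [cohort_config()].
#' @return List of [patient_record()] objects, CR patients first.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  base <- config$base_spec
  max_radius <- 0.95 * min((base$grid_shape - 1) / 2 * base$voxel_spacing_mm)
  # lower truncation: keep a small voxel cluster (with in-plane pairs)
  # even in the far lower tail of the per-patient size distribution
  min_radius <- 1.5 * max(base$voxel_spacing_mm)
  n <- config$n_cr + config$n_noncr
  with_private_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      cr <- i <= config$n_cr
      g <- if (cr) 1L else 2L
      mult <- function(m) if (cr) 1 else m
      radius <- min(max_radius, max(min_radius,
        base$tumor_radius_mm * mult(config$size_multiplier) *
          exp(stats::rnorm(1, sd = config$radius_sdlog))))
      intensity <- base$base_intensity *
        mult(config$intensity_multiplier) *
        exp(stats::rnorm(1, sd = config$intensity_sdlog))
      spec <- phantom_spec(
        grid_shape = base$grid_shape,
        voxel_spacing_mm = base$voxel_spacing_mm,
        tumor_radius_mm = radius,
        base_intensity = intensity,
        heterogeneity_sd = base$heterogeneity_sd *
          mult(config$heterogeneity_multiplier) *
          exp(stats::rnorm(1, sd = config$heterogeneity_sdlog)),
        correlation_length_mm = base$correlation_length_mm,
        # background keeps the spec's tumor-to-background ratio
        background_intensity = intensity *
          base$background_intensity / base$base_intensity)
      ph <- generate_phantom(spec,
                             seed = sample.int(.Machine$integer.max, 1))
      pet_mask2 <- perturb_mask_boundary(ph$mask, config$reader2_perturbation)
      ct <- make_ct_slice(ph$volume, ph$mask, config$ct_noise_sd)
      zc <- ceiling(dim(ph$volume$values)[1] / 2)
      ct_mask2 <- roi_mask(pet_mask2$flags[zc, , , drop = FALSE],
                           pet_mask2$spacing_mm)
      if (!any(ct_mask2$flags)) ct_mask2 <- ct$mask
      deauville <- if (cr) {
        sample(1:3, 1, prob = config$deauville_weights_cr)
      } else {
        sample(4:5, 1, prob = config$deauville_weights_noncr)
      }
      stage <- sample(VALID_STAGES, 1, prob = config$p_stage[, g])
      ipi <- if (stats::runif(1) < config$p_ipi_high[g]) {
        sample(3:5, 1, prob = c(7, 2, 0.5))
      } else {
        sample(0:2, 1, prob = c(9, 9, 3))
      }
      ki67 <- if (stats::runif(1) < config$p_ki67_high[g]) {
        round(stats::runif(1, 80, 95))
      } else {
        round(stats::runif(1, 40, 79))
      }
      patient_record(
        id = sprintf("P%03d", i),
        pet = ph$volume, pet_mask = ph$mask, pet_mask_reader2 = pet_mask2,
        ct_slice = ct$slice, ct_mask = ct$mask, ct_mask_reader2 = ct_mask2,
        stage = stage, ipi = ipi,
        intestinal_involvement = stats::runif(1) < config$p_intestinal[g],
        ki67_percent = ki67,
        subtype = if (stats::runif(1) < config$p_gcb[g]) "GCB" else "nonGCB",
        deauville = deauville)
    })
  })
}
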