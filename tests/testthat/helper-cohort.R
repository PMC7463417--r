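# Small, fast cohort configurations for tests.

tiny_spec <- function(grid = 16L, radius = 10, het = 0.25) {
  phantom_spec(grid_shape = rep(grid, 3), tumor_radius_mm = radius,
               heterogeneity_sd = het)
}

tiny_cohort <- function(n_cr = 8L, n_noncr = 6L, seed = 42L, ...) {
  generate_cohort(cohort_config(n_cr = n_cr, n_noncr = n_noncr,
                                base_spec = tiny_spec(), seed = seed, ...))
}
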