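# First-order and co-occurrence features against brute-force oracles and
# closed forms.

test_that("constant input gives the degenerate first-order vector", {
  fo <- first_order_features(rep(42, 50))
  expect_identical(unname(fo["sd"]), 0)
  expect_identical(unname(fo["entropy"]), 0)
  expect_identical(unname(fo["max_frequency"]), 50)
  expect_true(all(fo[c("minimum", "p5", "p25", "p50", "p75", "p90",
                       "maximum", "mean", "mode")] == 42))
  expect_true(isTRUE(attr(fo, "degenerate")))
})

test_that("a uniform 256-level histogram has 8 bits of entropy", {
  x <- seq(0, 255)
  fo <- first_order_features(x, discretization_spec(n_bins = 256))
  expect_equal(unname(fo["entropy"]), 8, tolerance = 1e-12)
})

test_that("first-order features match the naive oracle on random data", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- stats::rlnorm(500, meanlog = 8, sdlog = 0.5)
    fo <- first_order_features(x)
    expect_equal(fo[names(oracle_first_order(x))], oracle_first_order(x),
                 tolerance = 1e-10)
  }
})

test_that("first-order features transform correctly under affine maps", {
  set.seed(4)
  x <- stats::rnorm(300, 100, 15)
  a <- 2.5; b <- 40
  fo <- first_order_features(x, discretization_spec(
    integer_quantize_for_mode = FALSE))
  fo2 <- first_order_features(a * x + b, discretization_spec(
    integer_quantize_for_mode = FALSE))
  affine <- c("mean", "minimum", "maximum", "p5", "p10", "p25", "p50",
              "p75", "p90")
  expect_equal(unname(fo2[affine]), unname(a * fo[affine] + b),
               tolerance = 1e-9)
  expect_equal(unname(fo2["sd"]), unname(a * fo["sd"]), tolerance = 1e-9)
  # min-max binning preserves bin membership: entropy invariant
  expect_equal(unname(fo2["entropy"]), unname(fo["entropy"]),
               tolerance = 1e-9)
})

test_that("single-voxel ROI warns and reports sd 0", {
  expect_warning(fo <- first_order_features(3.5), "single-voxel")
  expect_identical(unname(fo["sd"]), 0)
})

test_that("constant region co-occurrence collapses to one diagonal cell", {
  d <- c(1, 4, 4)
  vol <- image_volume(array(9, d), c(4, 4, 4))
  mask <- roi_mask(array(TRUE, d), c(4, 4, 4))
  g <- glcm_matrix(vol, mask, glcm_spec(direction = 10),
                   discretization_spec(n_bins = 8))
  expect_identical(sum(g$P > 0), 1L)
  expect_identical(g$P[1, 1], 1)
  expect_equal(glcm_features(g),
               c(entropy_glcm = 0, energy_glcm = 1, inertia_glcm = 0,
                 variance_glcm = 0))
})

test_that("a two-level checkerboard puts all mass off the diagonal", {
  vals <- array(c(0, 100, 100, 0), c(1, 2, 2))
  vol <- image_volume(vals, c(4, 4, 4))
  mask <- roi_mask(array(TRUE, c(1, 2, 2)), c(4, 4, 4))
  g <- glcm_matrix(vol, mask, glcm_spec(direction = 10),
                   discretization_spec(n_bins = 2))
  expect_equal(g$P[1, 2], 0.5)
  expect_equal(g$P[2, 1], 0.5)
  expect_equal(g$P[1, 1] + g$P[2, 2], 0)
})

test_that("co-occurrence matrices are normalized, symmetric, and match the
           triple-loop oracle in all four directions", {
  offsets <- list(`10` = c(0, 1), `11` = c(1, 1), `12` = c(1, 0),
                  `13` = c(1, -1))
  for (seed in 1:3) {
    fx <- random_phantom_fixture(seed)
    for (dir in names(offsets)) {
      g <- glcm_matrix(fx$volume, fx$mask, glcm_spec(direction = dir),
                       discretization_spec(n_bins = 16))
      expect_equal(sum(g$P), 1, tolerance = 1e-12)
      expect_equal(g$P, t(g$P), tolerance = 0)
      expect_equal(g$P, oracle_glcm(fx$vals, fx$flags, offsets[[dir]], 16),
                   tolerance = 1e-12)
    }
  }
})

test_that("co-occurrence statistics match the double-loop oracle", {
  # closed form: uniform P over k^2 cells
  k <- 8
  u <- matrix(1 / k^2, k, k)
  f <- glcm_features(u)
  expect_equal(unname(f["energy_glcm"]), 1 / k^2, tolerance = 1e-12)
  expect_equal(unname(f["entropy_glcm"]), 2 * log2(k), tolerance = 1e-12)
  # random normalized matrices
  for (seed in 1:3) {
    set.seed(seed)
    P <- matrix(stats::rexp(64), 8, 8)
    P <- P / sum(P)
    expect_equal(glcm_features(P), oracle_glcm_features(P),
                 tolerance = 1e-12)
  }
  expect_error(glcm_features(matrix(1, 2, 2)),
               class = "pettex_domain_error")
})

test_that("energy and entropy respect their occupancy bounds", {
  for (seed in 1:5) {
    fx <- random_phantom_fixture(seed + 20)
    g <- glcm_matrix(fx$volume, fx$mask, glcm_spec(direction = 11),
                     discretization_spec(n_bins = 32))
    f <- glcm_features(g)
    k_occ <- sum(rowSums(g$P) > 0)
    expect_gte(f[["energy_glcm"]], 1 / k_occ^2 - 1e-12)
    expect_lte(f[["entropy_glcm"]], 2 * log2(k_occ) + 1e-12)
  }
})

test_that("more heterogeneity raises entropy and lowers co-occurrence
           energy", {
  calm <- generate_phantom(tiny_spec(het = 0.05), seed = 31)
  wild <- generate_phantom(tiny_spec(het = 0.6), seed = 31)
  fo_calm <- first_order_features(masked_values(calm$volume, calm$mask))
  fo_wild <- first_order_features(masked_values(wild$volume, wild$mask))
  expect_gt(fo_wild[["entropy"]], fo_calm[["entropy"]])
  e_calm <- glcm_features(glcm_matrix(calm$volume, calm$mask))
  e_wild <- glcm_features(glcm_matrix(wild$volume, wild$mask))
  expect_lt(e_wild[["energy_glcm"]], e_calm[["energy_glcm"]])
})

test_that("patient extraction is deterministic and reader-consistent", {
  co <- tiny_cohort(n_cr = 2, n_noncr = 2, seed = 55)
  r <- co[[1]]
  expect_identical(extract_patient_features(r),
                   extract_patient_features(r))
  # identical reader masks give identical features
  r2 <- r
  r2$pet_mask_reader2 <- r$pet_mask
  r2$ct_mask_reader2 <- r$ct_mask
  expect_identical(extract_patient_features(r2, reader = 1),
                   extract_patient_features(r2, reader = 2))
})

test_that("doubling the tumor radius scales the ROI volume about 8-fold", {
  small <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 24),
                                         tumor_radius_mm = 11), seed = 6)
  big <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 24),
                                       tumor_radius_mm = 22), seed = 6)
  ratio <- roi_volume(big$mask) / roi_volume(small$mask)
  expect_lt(abs(ratio - 8), 0.2 * 8)
})
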