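# Phantom and cohort generator: determinism, geometry, group structure.

test_that("noise-free phantom is exactly uniform inside the tumor", {
  spec <- phantom_spec(grid_shape = c(12, 12, 12), tumor_radius_mm = 10,
                       base_intensity = 5000, heterogeneity_sd = 0,
                       background_intensity = 0)
  ph <- generate_phantom(spec, seed = 3)
  v <- masked_values(ph$volume, ph$mask)
  expect_true(all(v == 5000))
  expect_true(all(ph$volume$values[!ph$mask$flags] == 0))
  fo <- first_order_features(v)
  expect_identical(unname(fo["sd"]), 0)
  expect_identical(unname(fo["entropy"]), 0)
})

test_that("phantom generation is deterministic and seed-sensitive", {
  spec <- tiny_spec()
  a <- generate_phantom(spec, seed = 7)
  b <- generate_phantom(spec, seed = 7)
  c <- generate_phantom(spec, seed = 8)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask$flags, b$mask$flags)
  expect_false(identical(a$volume$values, c$volume$values))
})

test_that("sphere mask voxel count matches the lattice-point count", {
  spec <- phantom_spec(grid_shape = c(15, 15, 15), tumor_radius_mm = 20)
  ph <- generate_phantom(spec, seed = 1)
  # brute-force: count voxel centers inside the sphere
  coords <- (1:15 - 8) * 4
  inside <- 0L
  for (z in coords) for (y in coords) for (x in coords) {
    if (z^2 + y^2 + x^2 <= 20^2) inside <- inside + 1L
  }
  expect_identical(sum(ph$mask$flags), inside)
  # and within 15% of the continuum volume (4/3) pi 20^3 / 64
  expect_lt(abs(sum(ph$mask$flags) - 4 / 3 * pi * 20^3 / 64),
            0.15 * 4 / 3 * pi * 20^3 / 64)
})

test_that("a tumor that does not fit the grid is rejected", {
  expect_error(phantom_spec(grid_shape = c(10, 10, 10),
                            tumor_radius_mm = 40),
               class = "pettex_geometry_error")
  expect_error(phantom_spec(base_intensity = 10,
                            background_intensity = 20),
               class = "pettex_domain_error")
})

test_that("cohort has the configured size, labels and Deauville scores", {
  co <- tiny_cohort(n_cr = 8, n_noncr = 6)
  expect_length(co, 14)
  resp <- vapply(co, `[[`, "", "response")
  expect_identical(sum(resp == "CR"), 8L)
  dv <- vapply(co, `[[`, 1L, "deauville")
  expect_true(all(dv[resp == "CR"] %in% 1:3))
  expect_true(all(dv[resp == "nonCR"] %in% 4:5))
  for (r in co) {
    expect_s3_class(r, "patient_record")
    expect_identical(dim(r$ct_slice$values)[1], 1L)
    expect_true(any(r$pet_mask_reader2$flags))
  }
})

test_that("cohort generation is a pure function of the config", {
  a <- tiny_cohort(seed = 11)
  b <- tiny_cohort(seed = 11)
  expect_identical(lapply(a, `[[`, "pet"), lapply(b, `[[`, "pet"))
  expect_identical(vapply(a, `[[`, 1L, "ipi"), vapply(b, `[[`, 1L, "ipi"))
  # and does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(tiny_cohort(seed = 5)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("null configuration produces no systematic group difference", {
  reps <- 100
  rej <- 0
  for (i in seq_len(reps)) {
    cfg <- cohort_config(
      n_cr = 12, n_noncr = 12,
      base_spec = phantom_spec(grid_shape = c(12, 12, 12),
                               tumor_radius_mm = 8),
      intensity_multiplier = 1, size_multiplier = 1,
      heterogeneity_multiplier = 1, seed = 1000 + i)
    co <- generate_cohort(cfg)
    suv <- vapply(co, function(r) suv_max(r$pet, r$pet_mask), 0)
    cr <- vapply(co, `[[`, "", "response") == "CR"
    p <- mann_whitney_u(suv[cr], suv[!cr])$p_value
    if (p < 0.05) rej <- rej + 1
  }
  # binomial(100, 0.05): 3 sd band around the nominal rate
  expect_lte(rej / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("effect multipliers push intensity, size and entropy up in non-CR", {
  hits <- c(mean = 0, volume = 0, entropy = 0)
  reps <- 10
  for (i in seq_len(reps)) {
    cfg <- cohort_config(
      n_cr = 30, n_noncr = 30,
      base_spec = phantom_spec(grid_shape = c(12, 12, 12),
                               tumor_radius_mm = 7),
      intensity_multiplier = 1.8, size_multiplier = 1.5,
      heterogeneity_multiplier = 1.6, seed = 7000 + i)
    co <- generate_cohort(cfg)
    cr <- vapply(co, `[[`, "", "response") == "CR"
    stats <- vapply(co, function(r) {
      v <- masked_values(r$pet, r$pet_mask)
      fo <- suppressWarnings(first_order_features(v))
      c(fo["mean"], volume = roi_volume(r$pet_mask), fo["entropy"])
    }, numeric(3))
    med <- function(k) stats::median(stats[k, !cr]) >
      stats::median(stats[k, cr])
    hits <- hits + c(med(1), med(2), med(3))
  }
  expect_true(all(hits >= reps - 1))
})

test_that("boundary perturbation respects its contract", {
  ph <- generate_phantom(tiny_spec(), seed = 2)
  set.seed(1)
  same <- perturb_mask_boundary(ph$mask, 0)
  expect_identical(same$flags, ph$mask$flags)
  pert <- perturb_mask_boundary(ph$mask, 0.5)
  expect_true(any(pert$flags))
  expect_false(identical(pert$flags, ph$mask$flags))
  # interior voxels (all 6 neighbours inside) are never removed
  m <- ph$mask$flags
  d <- dim(m)
  interior <- array(FALSE, d)
  for (z in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (x in 2:(d[3] - 1)) {
    interior[z, y, x] <- m[z, y, x] &&
      m[z - 1, y, x] && m[z + 1, y, x] && m[z, y - 1, x] &&
      m[z, y + 1, x] && m[z, y, x - 1] && m[z, y, x + 1]
  }
  expect_true(any(interior))
  expect_true(all(pert$flags[interior]))
})

test_that("cohort configs round-trip through YAML", {
  cfg <- cohort_config(n_cr = 5, n_noncr = 4, seed = 123,
                       base_spec = tiny_spec(grid = 14, radius = 9))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back, cfg, tolerance = 1e-12)
  expect_identical(generate_cohort(back)[[3]]$pet$values,
                   generate_cohort(cfg)[[3]]$pet$values)
})
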