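# Feature selection, ROC/DeLong, the logistic prediction probability and
# its calibration test.

test_that("the univariate filter keeps separated features and drops
           constant ones", {
  set.seed(10)
  labels <- rep(c("CR", "nonCR"), c(20, 10))
  feats <- data.frame(
    separated = c(stats::rnorm(20, 0), stats::rnorm(10, 10)),
    null = stats::rnorm(30),
    constant = rep(3, 30))
  expect_warning(res <- univariate_filter(feats, labels), "constant")
  expect_true("separated" %in% res$retained)
  expect_true("constant" %in% res$eliminated)
  expect_equal(res$p_values[["constant"]], 1)
  # rank-based filter: invariant to monotone transforms
  feats2 <- feats
  feats2$separated <- exp(feats$separated / 5)
  res2 <- suppressWarnings(univariate_filter(feats2, labels))
  expect_equal(res2$p_values[["separated"]],
               res$p_values[["separated"]])
})

test_that("the default category map reproduces the four groupings", {
  nm <- c("pet_mean", "pet_p50", "pet_maximum", "pet_sd",
          "pet_max_frequency", "ct_max_frequency", "pet_volume_mm3",
          "pet_max_diameter_mm", "ct_max_diameter_mm", "pet_entropy",
          "pet_entropy_glcm10", "pet_energy_glcm13", "ct_skewness",
          "suvmax", "mtv_mm3")
  cats <- feature_categories(nm)
  expect_identical(unname(cats["pet_mean"]), "uptake_intensity")
  expect_identical(unname(cats["pet_p50"]), "uptake_intensity")
  expect_identical(unname(cats["pet_sd"]), "intensity_distribution")
  expect_identical(unname(cats["ct_max_frequency"]),
                   "intensity_distribution")
  expect_identical(unname(cats["pet_volume_mm3"]), "tumor_size")
  expect_identical(unname(cats["ct_max_diameter_mm"]), "tumor_size")
  expect_identical(unname(cats["pet_entropy"]), "heterogeneity")
  expect_identical(unname(cats["pet_energy_glcm13"]), "heterogeneity")
  expect_identical(unname(cats["suvmax"]), "excluded")
  expect_identical(unname(cats["mtv_mm3"]), "excluded")
})

test_that("per-category selection takes the lowest p and breaks ties by
           distribution shape", {
  p <- c(pet_mean = 0.028, pet_p50 = 0.028, pet_p75 = 0.035,
         pet_entropy = 0.007, pet_energy_glcm10 = 0.049,
         pet_volume_mm3 = 0.006)
  normality <- c(pet_mean = 0.001, pet_p50 = 0.001, pet_p75 = 0.2,
                 pet_entropy = 0.4, pet_energy_glcm10 = 0.4,
                 pet_volume_mm3 = 0.01)
  sel <- select_per_category(p, normality_p = normality,
                             tie_tolerance = 1e-9)
  # mean and p50 tie; grey levels non-normal -> the percentile wins
  expect_identical(unname(sel["uptake_intensity"]), "pet_p50")
  expect_identical(unname(sel["heterogeneity"]), "pet_entropy")
  expect_identical(unname(sel["tumor_size"]), "pet_volume_mm3")
  # under normality the moment-type feature wins the tie
  sel2 <- select_per_category(p, normality_p = NULL)
  expect_identical(unname(sel2["uptake_intensity"]), "pet_mean")
  # single survivor is selected regardless of p
  sel3 <- select_per_category(c(pet_sd = 0.9))
  expect_identical(unname(sel3["intensity_distribution"]), "pet_sd")
})

test_that("ROC handles separation, null markers, and orientation", {
  labels <- rep(c("CR", "nonCR"), each = 10)
  sep <- c(stats::rnorm(10, 0, 0.1), stats::rnorm(10, 10, 0.1))
  r <- roc_analysis(sep, labels)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1)

  set.seed(11)
  null <- stats::rnorm(2000)
  big_labels <- sample(rep(c("CR", "nonCR"), each = 1000))
  expect_lt(abs(roc_analysis(null, big_labels)$auc - 0.5), 0.05)

  # lower-is-positive markers are auto-oriented
  flipped <- roc_analysis(-sep, labels)
  expect_equal(flipped$auc, r$auc)
  expect_identical(flipped$direction, "lower-is-positive")
  expect_equal(flipped$cutoff, -r$cutoff)
})

test_that("trapezoid AUC equals the rank statistic U/(n1 n2)", {
  set.seed(12)
  for (i in 1:20) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    vals <- c(round(stats::rnorm(n1, 1), 1), round(stats::rnorm(n0), 1))
    labels <- rep(c("nonCR", "CR"), c(n1, n0))
    auc <- roc_analysis(vals, labels)$auc
    u <- mann_whitney_u(vals[labels == "nonCR"],
                        vals[labels == "CR"])$statistic
    expect_equal(max(auc, 1 - auc), max(u, n1 * n0 - u) / (n1 * n0),
                 tolerance = 1e-12)
  }
})

test_that("the reported cutoff maximizes the Youden index", {
  set.seed(13)
  vals <- c(stats::rnorm(30, 1.2), stats::rnorm(20))
  labels <- rep(c("nonCR", "CR"), c(30, 20))
  r <- roc_analysis(vals, labels)
  pos <- labels == "nonCR"
  j <- vapply(sort(unique(vals)), function(t) {
    mean(vals[pos] > t) + mean(vals[!pos] <= t) - 1
  }, 0)
  expect_equal(r$sensitivity + r$specificity - 1, max(j),
               tolerance = 1e-12)
})

test_that("DeLong comparison: identity, rank invariance, and agreement
           with pROC", {
  set.seed(14)
  labels <- rep(c("nonCR", "CR"), c(15, 25))
  a <- c(stats::rnorm(15, 1), stats::rnorm(25))
  same <- delong_compare(a, a, labels)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_compare(a, 2 * a + 3, labels)
  expect_equal(mono$p_value, 1)

  skip_if_not_installed("pROC")
  for (i in 1:5) {
    b <- a + stats::rnorm(40, sd = 1.2)
    mine <- delong_compare(a, b, labels)
    ref <- pROC::roc.test(
      pROC::roc(labels, a, levels = c("CR", "nonCR"), direction = "<",
                quiet = TRUE),
      pROC::roc(labels, b, levels = c("CR", "nonCR"), direction = "<",
                quiet = TRUE),
      method = "delong")
    expect_equal(abs(mine$statistic), abs(unname(ref$statistic)),
                 tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("the logistic fit matches the closed-form log odds ratio and
           glm", {
  # single binary predictor: coefficient = log OR of the 2x2 table
  x <- data.frame(exposed = rep(c(1, 1, 0, 0), c(8, 12, 14, 6)))
  y <- rep(c("nonCR", "CR", "nonCR", "CR"), c(8, 12, 14, 6))
  fit <- fit_prediction_probability(x, y)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["exposed"]),
               log((8 / 12) / (14 / 6)), tolerance = 1e-8)

  set.seed(15)
  df <- data.frame(a = stats::rnorm(200), b = stats::rlnorm(200))
  eta <- -0.5 + 0.8 * df$a - 0.2 * df$b
  yy <- stats::rbinom(200, 1, stats::plogis(eta))
  fit2 <- fit_prediction_probability(df, yy)
  ref <- stats::glm(yy ~ a + b, data = df, family = stats::binomial())
  expect_equal(unname(coef(fit2)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit2$vcov))),
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-5)
  expect_equal(unname(predict(fit2, df)), unname(stats::fitted(ref)),
               tolerance = 1e-6)
})

test_that("separation is flagged but probabilities are still returned", {
  x <- data.frame(v = c(rep(0, 10), rep(1, 10)))
  y <- rep(c("CR", "nonCR"), each = 10)
  expect_warning(fit <- fit_prediction_probability(x, y), "separation")
  expect_true(fit$separated)
  expect_false(fit$converged)
  expect_true(all(fit$fitted >= 0 & fit$fitted <= 1))
  expect_gt(mean(fit$fitted[y == "nonCR"]), mean(fit$fitted[y == "CR"]))
})

test_that("null predictors give a chance-level prediction probability", {
  set.seed(16)
  x <- data.frame(a = stats::rnorm(400), b = stats::rnorm(400))
  y <- sample(rep(c("CR", "nonCR"), each = 200))
  fit <- fit_prediction_probability(x, y)
  expect_lt(abs(roc_analysis(fit$fitted, y)$auc - 0.5), 0.1)
})

test_that("Hosmer-Lemeshow flags gross miscalibration", {
  set.seed(17)
  p <- stats::runif(2000, 0.05, 0.95)
  y <- stats::rbinom(2000, 1, p)
  hits <- 0
  for (i in 1:5) {
    yy <- stats::rbinom(2000, 1, p)
    if (hosmer_lemeshow(p^2, yy)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 4)
  r <- hosmer_lemeshow(p, y)
  expect_identical(r$df, 8L)
  expect_error(hosmer_lemeshow(rep(0.4, 100), rbinom(100, 1, 0.4)),
               class = "pettex_domain_error")
})

test_that("the end-to-end analysis object is deterministic and coherent", {
  co <- tiny_cohort(n_cr = 10, n_noncr = 8, seed = 77)
  fit1 <- suppressWarnings(interim_response_analysis(co))
  fit2 <- suppressWarnings(interim_response_analysis(co))
  expect_identical(fit1$selected, fit2$selected)
  expect_identical(fit1$roc_combined$auc, fit2$roc_combined$auc)
  expect_identical(coef(fit1), coef(fit2))

  expect_length(fit1$selected, length(unique(names(fit1$selected))))
  expect_lte(length(fit1$selected), 4)
  expect_s3_class(fit1$model, "prediction_probability")
  expect_true(all(fit1$icc$icc <= 1 + 1e-12, na.rm = TRUE))
  expect_output(print(fit1), "Interim response analysis")
  expect_output(summary(fit1), "ROC analyses")
  p <- predict(fit1)
  expect_length(p, 18)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the combined model beats the best single marker in most
           replicate cohorts", {
  wins <- 0
  reps <- 11
  for (i in seq_len(reps)) {
    cfg <- cohort_config(
      seed = 600 + i,
      base_spec = phantom_spec(grid_shape = c(24, 24, 24),
                               tumor_radius_mm = 12))
    fit <- suppressWarnings(
      interim_response_analysis(generate_cohort(cfg),
                                compute_icc = FALSE))
    best_single <- max(vapply(fit$roc, `[[`, 0, "auc"))
    if (fit$roc_combined$auc > best_single) wins <- wins + 1
  }
  expect_gt(wins, reps / 2)
})
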