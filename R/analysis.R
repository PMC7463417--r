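# End-to-end analysis: the package's central fitted object. Runs the full
# workflow on a cohort -- contingency analysis of the clinical factors,
# two-step texture-feature selection, ROC of SUVmax / MTV / selected
# features, the combined logistic prediction probability with calibration,
# MTV-vs-volume consistency, and interobserver agreement.

contingency_rows <- function(records) {
  get <- function(f) vapply(records, `[[`,
                            vector(mode(records[[1]][[f]]), 1L), f)
  cr <- get("response") == "CR"
  list(
    `Lugano stage` = list(levels = c("Stage I", "Stage II and IV"),
                          in_first = get("stage") == "I"),
    `IPI score` = list(levels = c("0-2", "3-5"),
                       in_first = get("ipi") <= 2),
    `Histological subtype` = list(levels = c("GCB", "nonGCB"),
                                  in_first = get("subtype") == "GCB"),
    `Intestinal involvement` = list(levels = c("Involved", "Not involved"),
                                    in_first = get("intestinal_involvement")),
    `Ki67` = list(levels = c("<80%", ">=80%"),
                  in_first = get("ki67_percent") < 80),
    cr = cr)
}

#' Contingency analysis of clinicopathological factors
#'
#' Builds the 2x2 table of each dichotomized clinical factor (Lugano stage
#' I vs II+IV, IPI 0--2 vs 3--5, GCB vs non-GCB, intestinal involvement,
#' Ki67 < 80% vs >= 80%) against CR / non-CR, with per-row CR rates and a
#' Fisher exact p-value.
#'
#' @param records List of [patient_record()] objects.
#' @param sidedness Sidedness of [fisher_exact()]; one-sided tail
#'   probabilities are what reproduce the published contingency table.
#' @return `data.frame` with one row per factor level.
#' @export
clinical_contingency <- function(records, sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  rows <- contingency_rows(records)
  cr <- rows$cr
  out <- lapply(setdiff(names(rows), "cr"), function(fac) {
    f <- rows[[fac]]
    tab <- matrix(c(sum(f$in_first & cr), sum(f$in_first & !cr),
                    sum(!f$in_first & cr), sum(!f$in_first & !cr)),
                  2, 2, byrow = TRUE)
    p <- fisher_exact(tab, sidedness)$p_value
    data.frame(characteristic = fac, level = f$levels,
               n_cr = tab[, 1], n_noncr = tab[, 2],
               cr_rate_percent = 100 * tab[, 1] / rowSums(tab),
               p_value = c(p, NA))
  })
  do.call(rbind, out)
}

#' Run the full interim-response analysis
#'
#' The package's central estimator. From a cohort of patient records it
#' computes the reader-1 feature table, the clinical contingency analysis,
#' per-feature normality tests, the two-step feature selection
#' (Mann--Whitney filter, then the best survivor per category), ROC
#' analyses for SUVmax, MTV and each selected feature, the combined
#' logistic prediction probability (SUVmax + first-order entropy + ROI
#' volume + intestinal involvement) with its Hosmer--Lemeshow calibration
#' and ROC, the MTV-vs-volume consistency tests (Wilcoxon signed rank and
#' DeLong), and the interobserver ICC of every feature.
#'
#' @param records List of [patient_record()] objects with both response
#'   classes present.
#' @param disc A [discretization_spec()].
#' @param glcm_distance GLCM offset length in voxels.
#' @param alpha Filter significance level (default 0.05).
#' @param mtv_fraction MTV threshold fraction (default 0.41).
#' @param fisher_sidedness Sidedness for the contingency analysis.
#' @param compute_icc Set `FALSE` to skip the reader-2 extraction and ICC
#'   table.
#' @return Object of class `interim_response_analysis`; see
#'   [summary.interim_response_analysis()].
#' @examples
#' \donttest{
#' cfg <- cohort_config(seed = 7,
#'   base_spec = phantom_spec(grid_shape = c(20, 20, 20),
#'                            tumor_radius_mm = 14))
#' fit <- interim_response_analysis(generate_cohort(cfg))
#' summary(fit)
#' }
#' @export
interim_response_analysis <- function(records,
                                      disc = discretization_spec(),
                                      glcm_distance = 1L,
                                      alpha = 0.05,
                                      mtv_fraction = 0.41,
                                      fisher_sidedness = c("one", "two"),
                                      compute_icc = TRUE) {
  fisher_sidedness <- match.arg(fisher_sidedness)
  features <- extract_cohort_features(records, disc, glcm_distance, 1L,
                                      mtv_fraction)
  labels <- features$response
  if (length(unique(labels)) < 2L) {
    pettex_error("cohort must contain both CR and non-CR patients",
                 "pettex_domain_error")
  }
  contingency <- clinical_contingency(records, fisher_sidedness)

  meta_cols <- c("id", "response", "intestinal_involvement")
  candidates <- setdiff(names(features), c(meta_cols, "suvmax", "mtv_mm3"))
  filter <- suppressWarnings(
    univariate_filter(features[candidates], labels, alpha))
  normality <- vapply(candidates, function(f) {
    tryCatch(shapiro_wilk(features[[f]])$p_value,
             pettex_error = function(e) NA_real_)
  }, numeric(1))
  selected <- select_per_category(
    filter$p_values[filter$retained],
    feature_categories(filter$retained),
    normality_p = normality)

  roc_markers <- c(suvmax = "suvmax", mtv_mm3 = "mtv_mm3",
                   stats::setNames(selected, selected))
  rocs <- lapply(roc_markers, function(f)
    roc_analysis(features[[f]], labels))
  roc_p <- vapply(roc_markers, function(f) {
    suppressWarnings(mann_whitney_u(features[[f]][labels == "nonCR"],
                                    features[[f]][labels == "CR"],
                                    "two")$p_value)
  }, numeric(1))

  predictors <- data.frame(
    suvmax = features$suvmax,
    pet_entropy = features$pet_entropy,
    pet_volume_mm3 = features$pet_volume_mm3,
    intestinal_involvement = features$intestinal_involvement)
  model <- suppressWarnings(fit_prediction_probability(predictors, labels))
  hl <- tryCatch(suppressWarnings(
    hosmer_lemeshow(model$fitted, labels)),
    pettex_error = function(e) NULL)
  roc_combined <- roc_analysis(model$fitted, labels)

  mtv_vs_volume <- list(
    wilcoxon = wilcoxon_signed_rank(features$mtv_mm3,
                                    features$pet_volume_mm3),
    delong = delong_compare(features$mtv_mm3, features$pet_volume_mm3,
                            labels))

  icc <- if (compute_icc) {
    features2 <- extract_cohort_features(records, disc, glcm_distance, 2L,
                                         mtv_fraction)
    feats <- setdiff(names(features), meta_cols)
    do.call(rbind, lapply(feats, function(f) {
      r <- tryCatch(icc_two_way(cbind(features[[f]], features2[[f]])),
                    pettex_error = function(e) NULL)
      data.frame(feature = f,
                 icc = if (is.null(r)) NA_real_ else r$icc,
                 band = if (is.null(r)) NA_character_ else r$band)
    }))
  } else NULL

  structure(list(features = features, contingency = contingency,
                 filter = filter, normality = normality,
                 selected = selected, roc = rocs,
                 roc_p = roc_p, roc_combined = roc_combined,
                 model = model, hosmer_lemeshow = hl,
                 mtv_vs_volume = mtv_vs_volume, icc = icc,
                 labels = labels, alpha = alpha,
                 params = list(disc = disc, glcm_distance = glcm_distance,
                               mtv_fraction = mtv_fraction,
                               fisher_sidedness = fisher_sidedness)),
            class = "interim_response_analysis")
}

roc_table <- function(x) {
  rows <- lapply(names(x$roc), function(f) {
    r <- x$roc[[f]]
    data.frame(parameter = f, cutoff = r$cutoff,
               sensitivity = r$sensitivity, specificity = r$specificity,
               accuracy = r$accuracy, auc = r$auc,
               p_value = unname(x$roc_p[f]))
  })
  rc <- x$roc_combined
  rows$combined <- data.frame(
    parameter = "prediction_probability", cutoff = rc$cutoff,
    sensitivity = rc$sensitivity, specificity = rc$specificity,
    accuracy = rc$accuracy, auc = rc$auc, p_value = NA)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.interim_response_analysis <- function(x, ...) {
  n <- table(x$labels)
  cat(sprintf(
    "Interim response analysis: %d patients (%d CR, %d non-CR)\n",
    length(x$labels), n[["CR"]], n[["nonCR"]]))
  cat(sprintf("  features retained by the filter: %d of %d\n",
              length(x$filter$retained), length(x$filter$p_values)))
  cat("  selected per category:\n")
  for (cat_name in names(x$selected)) {
    cat(sprintf("    %-22s %s\n", cat_name, x$selected[[cat_name]]))
  }
  cat(sprintf("  combined prediction probability AUC = %.3f\n",
              x$roc_combined$auc))
  invisible(x)
}

#' Summarize an interim-response analysis
#'
#' Prints the contingency analysis, the selection outcome, the ROC table
#' (cutoff, sensitivity, specificity, accuracy, AUC per marker), the
#' logistic coefficients with the Hosmer--Lemeshow calibration, the
#' MTV-vs-volume consistency tests, and the interobserver-agreement
#' breakdown.
#'
#' @param object An [interim_response_analysis()] object.
#' @param ... Unused.
#' @return `object`, invisibly.
#' @export
summary.interim_response_analysis <- function(object, ...) {
  x <- object
  print(x)
  cat("\nClinicopathological contingency (Fisher exact,",
      paste0(x$params$fisher_sidedness, "-sided):\n"))
  print(x$contingency, digits = 3, row.names = FALSE)
  cat("\nROC analyses (positive class: non-CR):\n")
  print(roc_table(x), digits = 3, row.names = FALSE)
  cat("\nCombined logistic model:\n")
  print(summary(x$model))
  if (!is.null(x$hosmer_lemeshow)) {
    print(x$hosmer_lemeshow)
  }
  cat("\nMTV vs volume:\n  ")
  print(x$mtv_vs_volume$wilcoxon)
  cat("  ")
  print(x$mtv_vs_volume$delong)
  if (!is.null(x$icc)) {
    cat("\nInterobserver agreement bands:\n")
    print(table(factor(x$icc$band, levels = names(ICC_BANDS))))
  }
  invisible(x)
}

#' @export
coef.interim_response_analysis <- function(object, ...) {
  coef(object$model)
}

#' @export
predict.interim_response_analysis <- function(object, newdata = NULL,
                                              ...) {
  predict(object$model, newdata, ...)
}

#' Plot the ROC curves of an analysis
#'
#' Overlays the ROC curves of SUVmax, MTV, the selected features, and the
#' combined prediction probability.
#'
#' @param x An [interim_response_analysis()] object.
#' @param ... Passed to [plot.ptx_roc()] for the first curve.
#' @export
plot.interim_response_analysis <- function(x, ...) {
  curves <- c(x$roc, list(prediction_probability = x$roc_combined))
  cols <- seq_along(curves)
  plot(curves[[1]], col = cols[1], ...)
  for (i in seq_along(curves)[-1]) plot(curves[[i]], add = TRUE,
                                        col = cols[i])
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols,
                   legend = sprintf("%s (AUC %.3f)", names(curves),
                                    vapply(curves, `[[`, 0, "auc")))
  invisible(x)
}
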