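# Empirical ROC analysis with Youden-index cutoffs, and the DeLong test
# for two correlated AUCs.

#' ROC analysis of a single marker
#'
#' Builds the empirical ROC over all threshold positions, with non-CR as
#' the positive class. The AUC is the trapezoidal area, which equals the
#' tie-corrected Mann--Whitney U divided by `n_pos * n_neg`. The marker is
#' auto-oriented so that the AUC is at least 0.5 (`direction` records
#' whether higher or lower values call non-CR). The reported cutoff
#' maximizes the Youden index J = sensitivity + specificity - 1 over the
#' observed values, ties broken toward higher sensitivity; a positive call
#' is a value strictly beyond the cutoff.
#'
#' @param values Numeric marker values.
#' @param labels `"CR"`/`"nonCR"` (or logical, `TRUE` = positive).
#' @param positive Positive class label (default `"nonCR"`).
#' @return Object of class `ptx_roc`: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `accuracy`, `direction`, the `curve` data frame, and
#'   class sizes.
#' @export
roc_analysis <- function(values, labels, positive = "nonCR") {
  pos <- if (is.logical(labels)) labels else labels == positive
  if (!any(pos) || all(pos)) {
    pettex_error("both classes must be present", "pettex_domain_error")
  }
  if (anyNA(values)) {
    pettex_error("marker values must not be missing",
                 "pettex_domain_error")
  }
  auc_of <- function(w) {
    thr <- c(Inf, sort(unique(w), decreasing = TRUE))
    tpr <- vapply(thr, function(t) mean(w[pos] > t), 0)
    fpr <- vapply(thr, function(t) mean(w[!pos] > t), 0)
    tpr <- c(tpr, 1); fpr <- c(fpr, 1)
    list(auc = sum(diff(fpr) * (utils::head(tpr, -1) +
                                  utils::tail(tpr, -1)) / 2),
         curve = data.frame(cutoff = c(thr, -Inf), fpr = fpr, tpr = tpr))
  }
  first <- auc_of(values)
  flip <- first$auc < 0.5
  w <- if (flip) -values else values
  oriented <- if (flip) auc_of(w) else first
  cand <- sort(unique(w))
  sens <- vapply(cand, function(t) mean(w[pos] > t), 0)
  spec <- vapply(cand, function(t) mean(w[!pos] <= t), 0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(sens[best])]
  cutoff_w <- cand[best]
  curve <- oriented$curve
  if (flip) curve$cutoff <- -curve$cutoff
  structure(list(
    auc = oriented$auc,
    cutoff = if (flip) -cutoff_w else cutoff_w,
    sensitivity = sens[best], specificity = spec[best],
    accuracy = (sens[best] * sum(pos) + spec[best] * sum(!pos)) /
      length(pos),
    direction = if (flip) "lower-is-positive" else "higher-is-positive",
    positive = if (is.logical(labels)) TRUE else positive,
    curve = curve, n_pos = sum(pos), n_neg = sum(!pos)),
    class = "ptx_roc")
}

#' @export
print.ptx_roc <- function(x, ...) {
  cat(sprintf(
    "ROC (%s, positive = %s): AUC = %.3f\n  cutoff %s (%s): sens %.2f, spec %.2f, accuracy %.2f\n",
    paste0(x$n_pos, "+", x$n_neg), format(x$positive), x$auc,
    format(x$cutoff, digits = 4), x$direction, x$sensitivity,
    x$specificity, x$accuracy))
  invisible(x)
}

#' @export
plot.ptx_roc <- function(x, add = FALSE, col = 1, lwd = 2, ...) {
  if (!add) {
    graphics::plot(x$curve$fpr, x$curve$tpr, type = "l", col = col,
                   lwd = lwd, xlab = "1 - specificity",
                   ylab = "Sensitivity", xlim = c(0, 1), ylim = c(0, 1),
                   ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(x$curve$fpr, x$curve$tpr, col = col, lwd = lwd, ...)
  }
  invisible(x)
}

# Placement values of the positives against the negatives (and vice
# versa) for one marker; the building block of the DeLong covariance.
delong_placements <- function(values, pos) {
  xp <- values[pos]; xn <- values[!pos]
  cmp <- outer(xp, xn, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two markers measured on the same patients using
#' the placement-value covariance estimator; Z = (AUC_a - AUC_b) / SE,
#' two-sided p from the normal distribution. Identical (or perfectly
#' rank-correlated) markers yield Z = 0, p = 1.
#'
#' @param values_a,values_b Paired marker values.
#' @param labels Class labels as in [roc_analysis()].
#' @param positive Positive class (default `"nonCR"`).
#' @return A `ptx_test` with the Z statistic; `$auc` holds both AUCs.
#' @export
delong_compare <- function(values_a, values_b, labels,
                           positive = "nonCR") {
  if (length(values_a) != length(values_b)) {
    pettex_error("markers must be paired on the same patients",
                 "pettex_domain_error")
  }
  pos <- if (is.logical(labels)) labels else labels == positive
  if (!any(pos) || all(pos)) {
    pettex_error("both classes must be present", "pettex_domain_error")
  }
  pa <- delong_placements(values_a, pos)
  pb <- delong_placements(values_b, pos)
  n1 <- sum(pos); n0 <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  z <- if (var_diff <= 1e-16) 0 else (pa$auc - pb$auc) / sqrt(var_diff)
  out <- ptx_test("DeLong paired AUC comparison", z,
                  normal_two_sided_p(z), "two", n = c(n1, n0))
  out$auc <- c(a = pa$auc, b = pb$auc)
  out
}
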