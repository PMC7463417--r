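# Two-step feature selection: a rank-based univariate filter, then one
# winner per clinical category.

#' Default feature-category map
#'
#' Assigns every feature name to one of four categories -- FDG uptake
#' intensity, distribution of grey-level intensity, tumor size, and
#' intratumor heterogeneity -- or to `excluded`. SUVmax and MTV bypass the
#' texture filter (they are always reported separately), so both map to
#' `excluded`; MTV is deliberately not a `tumor_size` candidate, the
#' manual-ROI volume is.
#'
#' @param feature_names Character vector of feature names.
#' @return Named character vector mapping each name to its category.
#' @export
feature_categories <- function(feature_names) {
  cat_of <- function(f) {
    if (f %in% c("suvmax", "mtv_mm3", "id", "response",
                 "intestinal_involvement")) return("excluded")
    if (grepl("glcm", f) || f %in% c("pet_entropy", "ct_entropy")) {
      return("heterogeneity")
    }
    if (grepl("volume_mm3$|max_diameter_mm$", f)) return("tumor_size")
    if (grepl("^pet_(mean|minimum|maximum|p[0-9]+)$", f)) {
      return("uptake_intensity")
    }
    if (grepl("^(pet|ct)_(sd|max_frequency|mode|skewness|kurtosis)$", f) ||
        grepl("^ct_(mean|minimum|maximum|p[0-9]+)$", f)) {
      return("intensity_distribution")
    }
    "excluded"
  }
  stats::setNames(vapply(feature_names, cat_of, ""), feature_names)
}

# Order-statistic / count-based features, preferred over moment-based ones
# when tied and the grey levels are not normally distributed.
is_rank_type <- function(feature_names) {
  grepl("(_|^)p[0-9]+$|mode$|max_frequency$|minimum$|maximum$|median",
        feature_names)
}

#' Univariate Mann--Whitney filter
#'
#' Tests every feature column for a CR vs non-CR difference with the
#' two-sided Mann--Whitney U test and retains those with p below `alpha`.
#' Constant columns get p = 1, are eliminated, and trigger a warning.
#'
#' @param features Data frame or matrix of numeric feature columns.
#' @param labels `"CR"`/`"nonCR"` vector (or logical, `TRUE` = nonCR).
#' @param alpha Retention threshold (default 0.05).
#' @param fdr Also report Benjamini--Hochberg adjusted p-values (default
#'   `FALSE`; the raw p-values always drive retention, matching the
#'   uncorrected design of the original analysis).
#' @return List with `p_values` (named, every candidate), `retained`,
#'   `eliminated` feature names, and `p_adjusted` when `fdr = TRUE`.
#' @export
univariate_filter <- function(features, labels, alpha = 0.05,
                              fdr = FALSE) {
  features <- as.data.frame(features)
  pos <- if (is.logical(labels)) labels else labels == "nonCR"
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    pettex_error("need at least 2 patients per class",
                 "pettex_domain_error")
  }
  p <- vapply(names(features), function(f) {
    v <- features[[f]]
    if (length(unique(v)) == 1L) {
      warning(sprintf("feature '%s' is constant: p = 1, eliminated", f))
      return(1)
    }
    mann_whitney_u(v[pos], v[!pos], "two")$p_value
  }, numeric(1))
  out <- list(p_values = p, retained = names(p)[p < alpha],
              eliminated = names(p)[p >= alpha])
  if (isTRUE(fdr)) out$p_adjusted <- stats::p.adjust(p, "BH")
  out
}

#' Pick the best surviving feature per category
#'
#' Within each category the surviving feature with the lowest filter
#' p-value is selected. Exact ties are broken in favour of the
#' rank/percentile-type feature when normality is rejected for any tied
#' feature, otherwise toward the moment-type feature. Empty categories are
#' skipped, so at most four features are returned.
#'
#' @param p_values Named p-values of the surviving features (from
#'   [univariate_filter()]).
#' @param categories Named category map; defaults to
#'   [feature_categories()] of the feature names.
#' @param normality_p Optional named Shapiro--Wilk p-values per feature;
#'   normality is "rejected" below `normality_alpha`.
#' @param normality_alpha Rejection level for normality (default 0.05).
#' @param tie_tolerance Two p-values closer than this tie (default 1e-9).
#' @return Named character vector: category -> selected feature name.
#' @export
select_per_category <- function(p_values,
                                categories = feature_categories(names(p_values)),
                                normality_p = NULL,
                                normality_alpha = 0.05,
                                tie_tolerance = 1e-9) {
  if (!length(p_values)) {
    pettex_error("no surviving features to select from",
                 "pettex_domain_error")
  }
  cats <- c("uptake_intensity", "intensity_distribution", "tumor_size",
            "heterogeneity")
  picks <- character(0)
  for (cat in cats) {
    members <- names(p_values)[categories[names(p_values)] == cat]
    if (!length(members)) next
    p <- p_values[members]
    tied <- members[p <= min(p) + tie_tolerance]
    pick <- if (length(tied) > 1L) {
      rejected <- if (is.null(normality_p)) rep(FALSE, length(tied)) else
        !is.na(normality_p[tied]) & normality_p[tied] < normality_alpha
      rank_type <- is_rank_type(tied)
      if (any(rejected) && any(rank_type)) tied[rank_type][1] else
        if (any(!rank_type)) tied[!rank_type][1] else tied[1]
    } else {
      tied
    }
    picks[cat] <- pick
  }
  picks
}
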