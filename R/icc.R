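# Interobserver agreement: ICC(2,1), two-way random effects, absolute
# agreement, single measurement -- the canonical design for two raters
# measuring the same continuous features on the same subjects.

ICC_BANDS <- c(poor = 0.200, fair = 0.400, moderate = 0.600,
               good = 0.800, excellent = 1.000)

icc_band <- function(icc) {
  names(ICC_BANDS)[which(icc <= ICC_BANDS + 1e-12)[1]]
}

#' Intraclass correlation for two raters
#'
#' Computes ICC(2,1) from the two-way ANOVA mean squares
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with subjects as random rows and raters as random columns, and assigns
#' the qualitative agreement band (poor <= 0.200 < fair <= 0.400 <
#' moderate <= 0.600 < good <= 0.800 < excellent).
#'
#' @param ratings Numeric matrix, `n_subjects` x 2 (one column per
#'   reader), no missing cells, `n_subjects >= 3`.
#' @return Object of class `ptx_icc`: list with `icc`, `band`, the mean
#'   squares, and `n`.
#' @export
icc_two_way <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 2L || nrow(ratings) < 3L || anyNA(ratings)) {
    pettex_error("need an n x 2 complete matrix with n >= 3",
                 "pettex_domain_error")
  }
  n <- nrow(ratings); k <- ncol(ratings)
  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  if (stats::var(row_means) == 0) {
    pettex_error("zero between-subject variance: ICC undefined",
                 "pettex_domain_error")
  }
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((ratings - grand)^2)
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- (ss_total - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) /
    (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  structure(list(icc = icc, band = icc_band(icc), ms_rows = ms_r,
                 ms_cols = ms_c, ms_error = ms_e, n = n),
            class = "ptx_icc")
}

#' @export
print.ptx_icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (%s agreement), n = %d subjects\n",
              x$icc, x$band, x$n))
  invisible(x)
}

#' Interobserver ICC for every feature in a cohort
#'
#' Extracts the feature table for both readers and computes ICC(2,1)
#' per feature. Features that are constant across subjects for both
#' readers are skipped with `NA`.
#'
#' @inheritParams extract_cohort_features
#' @return `data.frame` with columns `feature`, `icc`, `band`.
#' @export
interobserver_icc <- function(records, disc = discretization_spec(),
                              glcm_distance = 1L, mtv_fraction = 0.41) {
  f1 <- extract_cohort_features(records, disc, glcm_distance, 1L,
                                mtv_fraction)
  f2 <- extract_cohort_features(records, disc, glcm_distance, 2L,
                                mtv_fraction)
  feats <- setdiff(names(f1), c("id", "response",
                                "intestinal_involvement"))
  res <- lapply(feats, function(f) {
    icc <- tryCatch(icc_two_way(cbind(f1[[f]], f2[[f]])),
                    pettex_error = function(e) NULL)
    data.frame(feature = f,
               icc = if (is.null(icc)) NA_real_ else icc$icc,
               band = if (is.null(icc)) NA_character_ else icc$band)
  })
  do.call(rbind, res)
}
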