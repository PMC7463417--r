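# The statistical toolbox used by the workflow. Each test returns a
# uniform `ptx_test` record. Rank tests and the exact contingency test are
# implemented here (they drive the feature selection and the contingency
# analysis, and their sidedness/tie conventions matter); textbook
# distribution functions come from base R.

ptx_test <- function(method, statistic, p_value, sidedness, n = NA,
                     df = NA, note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, sidedness = sidedness, n = n, df = df,
                 note = note), class = "ptx_test")
}

#' @export
print.ptx_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, %s-sided p = %.4g\n", x$method,
              format(x$statistic, digits = 4), x$sidedness, x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
as.list.ptx_test <- function(x, ...) unclass(x)

#' Fisher's exact test for a 2x2 table
#'
#' Enumerates the hypergeometric distribution over all tables with the
#' observed margins. The one-sided p-value is the tail probability of the
#' observed top-left cell in the direction of the observed association;
#' the two-sided p-value sums the probabilities of all tables no more
#' probable than the observed one. A degenerate margin (an empty row or
#' column) yields p = 1 with a warning.
#'
#' @param table 2x2 matrix of nonnegative counts: rows = patient subgroup,
#'   columns = CR / non-CR.
#' @param sidedness `"two"` (default) or `"one"`.
#' @return A `ptx_test` with the odds-ratio-direction-free cell count as
#'   statistic.
#' @examples
#' # intestinal involvement vs response, one-sided
#' fisher_exact(matrix(c(6, 7, 14, 3), 2, byrow = TRUE), "one")$p_value
#' @export
fisher_exact <- function(table, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0) ||
      any(table != round(table))) {
    pettex_error("need a 2x2 table of nonnegative integer counts",
                 "pettex_domain_error")
  }
  a <- table[1, 1]
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); N <- sum(table)
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) {
    warning("degenerate margin: p = 1")
    return(ptx_test("Fisher exact", a, 1, sidedness, n = N,
                    note = "degenerate margin"))
  }
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- probs[support == a]
  p <- if (sidedness == "one") {
    expected <- r1 * c1 / N
    if (abs(a - expected) < 1e-12) 1  # no observed association
    else if (a < expected) sum(probs[support <= a])
    else sum(probs[support >= a])
  } else {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  ptx_test("Fisher exact", a, min(p, 1), sidedness, n = N)
}

#' Mann--Whitney U test
#'
#' U is computed from midranks (0.5 credit for ties). With pooled
#' n <= 12 and no ties the p-value is exact by enumeration of all rank
#' assignments; otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param x,y Nonempty numeric samples.
#' @param sidedness `"two"` (default) or `"one"` (direction of the
#'   observed shift).
#' @return A `ptx_test` with statistic U (for `x`).
#' @export
mann_whitney_u <- function(x, y, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (!length(x) || !length(y)) {
    pettex_error("both samples must be nonempty", "pettex_domain_error")
  }
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- any(duplicated(pooled))
  if (n1 + n2 <= 12L && !ties) {
    sets <- utils::combn(n1 + n2, n1)
    ranks_all <- seq_len(n1 + n2)
    us <- colSums(matrix(ranks_all[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- if (sidedness == "two") {
      mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    } else {
      if (u <= mu) mean(us <= u + 1e-12) else mean(us >= u - 1e-12)
    }
    return(ptx_test("Mann-Whitney U (exact)", u, p, sidedness,
                    n = c(n1, n2)))
  }
  tab <- table(pooled)
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(tab^3 - tab) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) {
    return(ptx_test("Mann-Whitney U (normal approx.)", u, 1, sidedness,
                    n = c(n1, n2), note = "all values tied"))
  }
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p_one <- stats::pnorm(z, lower.tail = FALSE)
  p <- if (sidedness == "two") min(2 * p_one, 1) else p_one
  ptx_test("Mann-Whitney U (normal approx.)", u, p, sidedness,
           n = c(n1, n2))
}

#' Wilcoxon signed rank test for paired samples
#'
#' Differences `x - y`; zero differences are dropped. Exact enumeration of
#' all sign patterns for fewer than 10 nonzero pairs, otherwise a normal
#' approximation with continuity and tie correction. The signed Z
#' statistic (positive when `x` tends to exceed `y`) is always reported.
#'
#' @param x,y Equal-length paired samples.
#' @param sidedness `"two"` (default) or `"one"`.
#' @return A `ptx_test` with the signed-rank sum `V` as statistic and the
#'   signed normal deviate in `$z`.
#' @export
wilcoxon_signed_rank <- function(x, y, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (length(x) != length(y)) {
    pettex_error("paired samples must have equal length",
                 "pettex_domain_error")
  }
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero: p = 1")
    out <- ptx_test("Wilcoxon signed rank", 0, 1, sidedness, n = 0,
                    note = "all differences zero")
    out$z <- 0
    return(out)
  }
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  z_signed <- if (sigma2 > 0) {
    sign(v - mu) * max(abs(v - mu) - 0.5, 0) / sqrt(sigma2)
  } else 0
  if (n < 10L && !any(duplicated(abs(d)))) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    p <- if (sidedness == "two") {
      mean(abs(vs - mu) >= abs(v - mu) - 1e-12)
    } else {
      if (v <= mu) mean(vs <= v + 1e-12) else mean(vs >= v - 1e-12)
    }
    out <- ptx_test("Wilcoxon signed rank (exact)", v, p, sidedness, n = n)
  } else {
    p_one <- stats::pnorm(abs(z_signed), lower.tail = FALSE)
    p <- if (sidedness == "two") min(2 * p_one, 1) else p_one
    out <- ptx_test("Wilcoxon signed rank (normal approx.)", v, p,
                    sidedness, n = n)
  }
  out$z <- z_signed
  out
}

#' Shapiro--Wilk normality test
#'
#' The W statistic with Royston's approximation to its null distribution
#' (as implemented in [stats::shapiro.test()]); valid for 3 <= n <= 5000.
#' Zero-variance samples are rejected as degenerate input.
#'
#' @param x Numeric sample.
#' @return A `ptx_test` with statistic W.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3L || length(x) > 5000L) {
    pettex_error("Shapiro-Wilk requires 3 <= n <= 5000",
                 "pettex_domain_error")
  }
  if (stats::sd(x) == 0) {
    pettex_error("Shapiro-Wilk undefined for a constant sample",
                 "pettex_domain_error")
  }
  sw <- stats::shapiro.test(x)
  ptx_test("Shapiro-Wilk", unname(sw$statistic), sw$p.value, "two",
           n = length(x))
}

#' Upper-tail chi-square probability
#'
#' @param statistic Nonnegative chi-square value.
#' @param df Positive degrees of freedom.
#' @return Upper-tail probability.
#' @examples
#' chi2_upper_tail(9.727, 8)  # ~0.285
#' @export
chi2_upper_tail <- function(statistic, df) {
  if (statistic < 0) {
    pettex_error("chi-square statistic must be nonnegative",
                 "pettex_domain_error")
  }
  stats::pchisq(statistic, df, lower.tail = FALSE)
}

#' Two-sided normal p-value
#'
#' `2 * (1 - pnorm(|z|))`.
#'
#' @param z Normal deviate.
#' @return Two-sided p-value.
#' @examples
#' normal_two_sided_p(0.227)  # ~0.820
#' @export
normal_two_sided_p <- function(z) {
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}
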