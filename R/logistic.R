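# The combined "prediction probability": an unpenalized binary logistic
# model fit by Newton-Raphson, and the Hosmer-Lemeshow calibration test.

#' Fit the combined logistic prediction probability
#'
#' Maximum-likelihood binary logistic regression of non-CR status on a
#' small set of predictors (classically SUVmax, first-order entropy, ROI
#' volume, and intestinal involvement), fit with Newton iterations until
#' the relative log-likelihood change falls below `tol` (default 1e-10) or
#' `max_iter` iterations. The fitted per-patient probability of non-CR is
#' the "prediction probability" that is then evaluated with
#' [roc_analysis()] and [hosmer_lemeshow()]. Perfect separation is
#' flagged: the fit is marked non-convergent and the last iterate's
#' probabilities are returned with a warning.
#'
#' @param x Data frame or matrix of predictors (numeric or logical
#'   columns; an intercept is added).
#' @param y Labels: `"CR"`/`"nonCR"`, logical, or 0/1 (`1` = non-CR).
#' @param positive Positive class when `y` is character.
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class `prediction_probability` with elements
#'   `coefficients`, `vcov`, `fitted` (P(non-CR)), `linear_predictors`,
#'   `loglik`, `converged`, `separated`, `iterations`, `y`.
#' @seealso [predict.prediction_probability()], [hosmer_lemeshow()]
#' @export
fit_prediction_probability <- function(x, y, positive = "nonCR",
                                       max_iter = 100L, tol = 1e-10) {
  x <- as.data.frame(x)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data.frame(lapply(x, as.numeric))))
  yy <- if (is.logical(y)) as.numeric(y) else if (is.numeric(y)) y else
    as.numeric(y == positive)
  if (anyNA(X) || anyNA(yy)) {
    pettex_error("missing values in predictors or labels",
                 "pettex_domain_error")
  }
  if (length(yy) < 10L) {
    pettex_error("need at least 10 patients to fit the model",
                 "pettex_domain_error")
  }
  if (all(yy == 0) || all(yy == 1)) {
    pettex_error("both outcome classes must be present",
                 "pettex_domain_error")
  }
  # numerically stable Bernoulli log-likelihood
  ll_of <- function(eta) {
    sum(yy * eta) - sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
  }
  beta <- rep(0, ncol(X))
  eta <- drop(X %*% beta)
  loglik <- ll_of(eta)
  converged <- FALSE
  iter <- 0L
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    H <- crossprod(X, X * w)
    step <- tryCatch(solve(H, crossprod(X, yy - p)),
                     error = function(e) NULL)
    if (is.null(step)) break
    beta_new <- beta + drop(step)
    eta_new <- drop(X %*% beta_new)
    ll_new <- ll_of(eta_new)
    # halve the step if the likelihood worsens (rare, far from optimum)
    halvings <- 0L
    while ((is.nan(ll_new) || ll_new < loglik) && halvings < 20L) {
      halvings <- halvings + 1L
      beta_new <- (beta + beta_new) / 2
      eta_new <- drop(X %*% beta_new)
      ll_new <- ll_of(eta_new)
    }
    if (is.nan(ll_new)) break
    done <- abs(ll_new - loglik) < tol * (abs(loglik) + tol)
    beta <- beta_new; eta <- eta_new; loglik <- ll_new
    if (done) { converged <- TRUE; break }
  }
  p <- stats::plogis(eta)
  # separation: fitted probabilities numerically at 0/1 together with a
  # diverging fit (no interior optimum, a perfect in-sample likelihood,
  # or runaway linear predictors); a merely extreme but interior fitted
  # probability does not qualify
  boundary <- min(p) < 1e-8 || max(p) > 1 - 1e-8
  separated <- boundary &&
    (!converged || loglik > -1e-6 || max(abs(eta)) > 100)
  if (separated) converged <- FALSE
  if (separated) {
    warning(paste("perfect or quasi-perfect separation:",
                  "coefficients are non-convergent;",
                  "probabilities from the last iterate"))
  } else if (!converged) {
    warning("Newton iterations did not converge")
  }
  vcov <- tryCatch(solve(crossprod(X, X * (p * (1 - p)))),
                   error = function(e) matrix(NA, ncol(X), ncol(X)))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = vcov, fitted = p, linear_predictors = eta,
                 loglik = loglik, converged = converged,
                 separated = separated, iterations = iter, y = yy,
                 predictors = colnames(X)[-1]),
            class = "prediction_probability")
}

#' @export
coef.prediction_probability <- function(object, ...) object$coefficients

#' @export
vcov.prediction_probability <- function(object, ...) object$vcov

#' @export
fitted.prediction_probability <- function(object, ...) object$fitted

#' Predict from a fitted prediction-probability model
#'
#' @param object A [fit_prediction_probability()] fit.
#' @param newdata Optional data frame with the model's predictors; the
#'   training probabilities are returned when absent.
#' @param type `"response"` (probability of non-CR) or `"link"`.
#' @param ... Unused.
#' @export
predict.prediction_probability <- function(object, newdata = NULL,
                                           type = c("response", "link"),
                                           ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(if (type == "response") object$fitted
           else object$linear_predictors)
  }
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing)) {
    pettex_error(paste("newdata lacks predictors:",
                       paste(missing, collapse = ", ")),
                 "pettex_domain_error")
  }
  X <- cbind(1, as.matrix(data.frame(
    lapply(newdata[object$predictors], as.numeric))))
  eta <- drop(X %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.prediction_probability <- function(object,
                                             type = c("deviance",
                                                      "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "response") return(r)
  sign(r) * sqrt(-2 * (object$y * log(object$fitted) +
                         (1 - object$y) * log(1 - object$fitted)))
}

#' @export
print.prediction_probability <- function(x, ...) {
  cat("Binary logistic prediction probability (positive = non-CR)\n")
  cat(sprintf("  n = %d, log-likelihood = %.3f, %s after %d iterations\n",
              length(x$y), x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.prediction_probability <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = normal_two_sided_p(z))
  out <- list(coefficients = tab, loglik = object$loglik,
              converged = object$converged, separated = object$separated,
              n = length(object$y))
  class(out) <- "summary.prediction_probability"
  out
}

#' @export
print.summary.prediction_probability <- function(x, ...) {
  cat(sprintf(
    "Logistic prediction probability: n = %d, logLik = %.3f%s\n", x$n,
    x$loglik, if (x$separated) " (separated!)" else ""))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Hosmer--Lemeshow calibration test
#'
#' Groups the patients into `n_groups` deciles of predicted risk and
#' compares observed with expected counts of both outcomes:
#' \eqn{\chi^2 = \sum_g \sum_{k \in \{0,1\}} (O_{gk}-E_{gk})^2 / E_{gk}},
#' with `n_groups - 2` degrees of freedom. Groups whose expected count is
#' zero for either outcome are merged with their neighbour (with a
#' warning).
#'
#' @param probabilities Predicted probabilities of the positive class.
#' @param labels Labels as in [roc_analysis()], or 0/1.
#' @param n_groups Number of risk groups (default 10).
#' @param positive Positive class when `labels` is character.
#' @return A `ptx_test` with the chi-square statistic and `df`.
#' @export
hosmer_lemeshow <- function(probabilities, labels, n_groups = 10L,
                            positive = "nonCR") {
  if (n_groups < 3L) {
    pettex_error("need at least 3 risk groups", "pettex_domain_error")
  }
  y <- if (is.logical(labels)) as.numeric(labels) else
    if (is.numeric(labels)) labels else as.numeric(labels == positive)
  if (any(probabilities < 0 | probabilities > 1)) {
    pettex_error("probabilities must lie in [0,1]", "pettex_domain_error")
  }
  breaks <- unique(stats::quantile(probabilities,
                                   seq(0, 1, length.out = n_groups + 1),
                                   type = 7))
  if (length(breaks) < 4L) {
    pettex_error("too few distinct probabilities to form risk groups",
                 "pettex_domain_error")
  }
  grp <- cut(probabilities, breaks, include.lowest = TRUE)
  o1 <- tapply(y, grp, sum)
  e1 <- tapply(probabilities, grp, sum)
  n_g <- tapply(y, grp, length)
  keep <- !is.na(n_g)
  o1 <- o1[keep]; e1 <- e1[keep]; n_g <- n_g[keep]
  # merge groups with a zero expected cell into the neighbour below
  while (length(n_g) > 3L && any(e1 <= 0 | (n_g - e1) <= 0)) {
    i <- which(e1 <= 0 | (n_g - e1) <= 0)[1]
    j <- if (i == 1L) 2L else i - 1L
    warning("merging a risk group with zero expected count")
    o1[j] <- o1[j] + o1[i]; e1[j] <- e1[j] + e1[i]
    n_g[j] <- n_g[j] + n_g[i]
    o1 <- o1[-i]; e1 <- e1[-i]; n_g <- n_g[-i]
  }
  chi2 <- sum((o1 - e1)^2 / e1 + ((n_g - o1) - (n_g - e1))^2 / (n_g - e1))
  df <- length(n_g) - 2L
  ptx_test("Hosmer-Lemeshow", chi2, chi2_upper_tail(chi2, df), "two",
           n = length(y), df = df)
}
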