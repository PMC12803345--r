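#' Harmonize CSF biomarker concentrations
#'
#' Flags log10-scale outliers with Tukey fences (Q1 - 1.5 IQR, Q3 + 1.5 IQR,
#' linear-interpolation quantiles) and z-standardizes the surviving values.
#' This mirrors the harmonization applied to CSF analytes before any
#' downstream modeling: biomarker concentrations are right-skewed, so
#' fencing is done on the log scale, while the returned z-scores are computed
#' on the log10 values that survive the fences.
#'
#' @param values Positive concentrations (e.g. pg/mL).
#' @return A list with `z` (z-scores for kept values, `NA` for excluded ones)
#'   and `kept` (logical mask). If the kept values have zero variance the
#'   z-scores are 0 by convention.
#' @examples
#' csf_harmonize(c(10, 11, 12, 13, 1000))$kept
#' @export
csf_harmonize <- function(values) {
  if (length(values) < 3) stop("need at least 3 values for IQR fencing")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be positive and finite")
  lx <- log10(values)
  q <- stats::quantile(lx, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  kept <- lx >= q[1] - 1.5 * iqr & lx <= q[2] + 1.5 * iqr
  z <- rep(NA_real_, length(values))
  z[kept] <- zscore_or_zero(lx[kept])
  list(z = z, kept = kept)
}

#' Two-component Gaussian-mixture cut point
#'
#' Fits a two-component univariate Gaussian mixture (unequal variances) and
#' returns the value between the component means at which the posterior
#' probability of membership is 0.5 — the data-driven threshold used, e.g.,
#' to call amyloid positivity from CSF z-scores. The equal-posterior
#' condition is a quadratic in the cut value and is solved in closed form
#' from the fitted mixture parameters; the root lying between the two means
#' is returned (the root nearest the midpoint if both fall outside).
#'
#' @param z Numeric observations (at least 20).
#' @return The scalar cut value, with the fitted mixture parameters attached
#'   as attribute `"mixture"`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, -1, 0.3), rnorm(300, 1, 0.3))
#' abs(gmm_cutpoint(x)) < 0.1
#' @export
gmm_cutpoint <- function(z) {
  if (length(z) < 20) stop("need at least 20 observations")
  bic <- mclust::mclustBIC(z, G = 2, modelNames = "V", verbose = FALSE)
  fit <- mclust::Mclust(z, G = 2, modelNames = "V", verbose = FALSE, x = bic)
  if (is.null(fit))
    stop("Gaussian mixture fit did not converge (mclust returned NULL); ",
         "n = ", length(z), ", range = [", min(z), ", ", max(z), "]")
  mns <- fit$parameters$mean
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1) sds <- rep(sds, 2)
  pro <- fit$parameters$pro
  o <- order(mns)
  m1 <- mns[o[1]]; m2 <- mns[o[2]]
  s1 <- sds[o[1]]; s2 <- sds[o[2]]
  p1 <- pro[o[1]]; p2 <- pro[o[2]]
  if (m2 - m1 < sqrt(.Machine$double.eps))
    stop("component means coincide; no cut point between components")
  ## equal-posterior condition: log(p1 phi(x; m1, s1)) = log(p2 phi(x; m2, s2))
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(p1 * s2 / (p2 * s1))
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) stop("degenerate mixture: no unique cut point")
    cut <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no real equal-posterior solution")
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    inside <- roots[roots >= m1 & roots <= m2]
    cut <- if (length(inside)) inside[1] else
      roots[which.min(abs(roots - (m1 + m2) / 2))]
  }
  attr(cut, "mixture") <- list(mean = c(m1, m2), sd = c(s1, s2),
                               weight = c(p1, p2),
                               loglik = fit$loglik)
  cut
}
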