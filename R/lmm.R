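#' Random-intercept linear mixed model by profiled REML
#'
#' Fits \eqn{y_{ij} = x_{ij}'\beta + b_i + \varepsilon_{ij}} with
#' \eqn{b_i \sim N(0, \sigma_b^2)} and \eqn{\varepsilon_{ij} \sim N(0,
#' \sigma^2)} by restricted maximum likelihood, profiling the criterion
#' down to the single variance ratio \eqn{\theta = \sigma_b^2/\sigma^2}.
#' For a given \eqn{\theta} the GLS solve reduces to ordinary least squares
#' on partially demeaned data (each subject's mean shrunk by
#' \eqn{1 - 1/\sqrt{1 + n_i\theta}}), so the one-dimensional profile is
#' cheap and the optimum is located by golden-section search on
#' \eqn{\log\theta}, with the boundary \eqn{\theta = 0} checked explicitly.
#'
#' Fixed-effect Wald t statistics use residual degrees of freedom
#' n_obs - n_fixed; this is a large-sample approximation, not a
#' Satterthwaite adjustment.
#'
#' @param formula Fixed-effects formula (e.g.
#'   `memory ~ age + sex + mrs * time`).
#' @param data One row per observation.
#' @param subject Name of the grouping column (default `"subject_id"`).
#' @return An object of class `lmm_fit`: `coefficients` (data.frame with
#'   `term`, `estimate`, `se`, `t`, `p`), `sigma_b`, `sigma`, `theta`,
#'   `reml_loglik`, `n_subjects`, `n_obs`, `boundary`, `vcov`, and
#'   `profile` (the -2 REML criterion as a function of theta).
#' @export
fit_random_intercept_lmm <- function(formula, data,
                                     subject = "subject_id") {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effects design (rank ", qr(X)$rank, " < ",
         ncol(X), " columns)")
  grp <- factor(data[[subject]])
  N <- length(y); p <- ncol(X); m <- nlevels(grp)
  gidx <- as.integer(grp)
  ni <- tabulate(gidx, m)
  ybar <- rowsum(y, gidx) / ni            # subject means, m x 1
  Xbar <- rowsum(X, gidx) / ni            # subject means, m x p

  crit <- function(theta) {
    ## -2 * restricted log-likelihood, profiled over beta and sigma^2;
    ## GLS reduces to OLS on partially subject-demeaned data
    c_shrink <- 1 - 1 / sqrt(1 + ni * theta)
    ys <- y - c_shrink[gidx] * ybar[gidx]
    Xs <- X - c_shrink[gidx] * Xbar[gidx, , drop = FALSE]
    qrx <- qr(Xs)
    rss <- sum(qr.resid(qrx, ys)^2)
    s2 <- rss / (N - p)
    ldV <- sum(log(1 + ni * theta))
    ldXVX <- 2 * sum(log(abs(diag(qr.R(qrx)))))
    val <- (N - p) * (1 + log(2 * pi * s2)) + ldV + ldXVX
    attr(val, "qrx") <- qrx
    attr(val, "ys") <- ys
    attr(val, "s2") <- s2
    val
  }

  opt <- stats::optimize(function(lt) as.numeric(crit(exp(lt))),
                         interval = c(-18, 12), tol = 1e-10)
  theta <- exp(opt$minimum)
  boundary <- FALSE
  if (as.numeric(crit(0)) <= opt$objective) {
    theta <- 0
    boundary <- TRUE
  }
  cv <- crit(theta)
  qrx <- attr(cv, "qrx")
  s2 <- attr(cv, "s2")
  beta <- qr.coef(qrx, attr(cv, "ys"))
  XtXi <- chol2inv(qr.R(qrx))
  V <- s2 * XtXi
  se <- sqrt(diag(V))
  tval <- beta / se
  df <- N - p
  coefs <- data.frame(term = colnames(X), estimate = as.numeric(beta),
                      se = se, t = as.numeric(tval),
                      p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  dimnames(V) <- list(colnames(X), colnames(X))
  out <- list(coefficients = coefs, sigma_b = sqrt(theta * s2),
              sigma = sqrt(s2), theta = theta,
              reml_loglik = -as.numeric(cv) / 2,
              n_subjects = m, n_obs = N, boundary = boundary,
              vcov = V, formula = formula,
              profile = function(th) as.numeric(crit(th)))
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Random-intercept LMM (REML): %d obs, %d subjects\n",
              x$n_obs, x$n_subjects))
  cat(sprintf("  sigma_b = %.4g, sigma = %.4g, REML logLik = %.4f%s\n",
              x$sigma_b, x$sigma, x$reml_loglik,
              if (x$boundary) " [variance at zero boundary]" else ""))
  cf <- x$coefficients
  cf[, -1] <- lapply(cf[, -1], signif, digits)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' Longitudinal memory model on the Methylation Reserve Score
#'
#' Assembles the canonical longitudinal model: memory on baseline age, sex,
#' APOE4, education, MRS, baseline pTau, time, and the MRS-by-time,
#' pTau-by-time and MRS-by-pTau interactions, with a subject random
#' intercept. Baseline age, pTau and MRS are z-scored across the analysis
#' sample before fitting, so their main effects describe a subject at the
#' sample mean. With `use_tertiles = TRUE` the continuous MRS is replaced
#' by low/mid indicator terms (high tertile as reference), reproducing the
#' group-wise re-fit.
#'
#' @param long Longitudinal table (`subject_id`, `visit_time`, `memory`).
#' @param pheno Baseline phenotype table (`subject_id`, `age`, `sex`,
#'   `apoe4`, `education`, `ptau_z`).
#' @param mrs An `mrs_result` from [compute_mrs()] (or any data.frame with
#'   `subject_id`, `mrs_z`, `tertile`).
#' @param use_tertiles Replace the continuous MRS with tertile indicators.
#' @return An `lmm_fit` (see [fit_random_intercept_lmm()]).
#' @export
fit_longitudinal_model <- function(long, pheno, mrs, use_tertiles = FALSE) {
  dat <- merge(long, pheno[, c("subject_id", "age", "sex", "apoe4",
                               "education", "ptau_z")], by = "subject_id")
  dat <- merge(dat, mrs[, c("subject_id", "mrs_z", "tertile")],
               by = "subject_id")
  if (anyNA(dat)) stop("incomplete covariates after joining tables")
  ## z-score the continuous baseline covariates over the analysis subjects
  sub <- !duplicated(dat$subject_id)
  zs <- function(v) (v - mean(v[sub])) / stats::sd(v[sub])
  dat$baseline_age <- zs(dat$age)
  dat$baseline_ptau <- zs(dat$ptau_z)
  dat$mrs <- zs(dat$mrs_z)
  dat$time <- dat$visit_time
  form <- if (use_tertiles) {
    dat$mrs_low <- as.numeric(dat$tertile == "low")
    dat$mrs_mid <- as.numeric(dat$tertile == "mid")
    memory ~ baseline_age + sex + apoe4 + education + mrs_low + mrs_mid +
      time + baseline_ptau + mrs_low:time + mrs_mid:time +
      baseline_ptau:time + mrs_low:baseline_ptau + mrs_mid:baseline_ptau
  } else {
    memory ~ baseline_age + sex + apoe4 + education + mrs + time +
      baseline_ptau + mrs:time + baseline_ptau:time + mrs:baseline_ptau
  }
  fit_random_intercept_lmm(form, dat)
}

#' Per-tertile change-from-baseline trajectories
#'
#' Computes each subject's change in memory from their baseline (time 0)
#' visit and, per MRS tertile, the OLS slope of change against time — the
#' group-level summary used to display differential decline.
#'
#' @param long Longitudinal table (`subject_id`, `visit_time`, `memory`);
#'   every subject should have a baseline row, subjects without one are
#'   dropped with a warning.
#' @param mrs Data.frame with `subject_id` and `tertile`.
#' @return A list with `series` (per-visit change scores with tertile) and
#'   `slopes` (per-group slope, SE, n_subjects).
#' @export
trajectory_summary <- function(long, mrs) {
  base <- long[long$visit_time == 0, c("subject_id", "memory")]
  names(base)[2] <- "memory0"
  miss <- setdiff(unique(long$subject_id), base$subject_id)
  if (length(miss))
    warning("subject(s) without baseline row excluded: ",
            paste(miss, collapse = ", "))
  ser <- merge(long, base, by = "subject_id")
  ser$change <- ser$memory - ser$memory0
  ser <- merge(ser, mrs[, c("subject_id", "tertile")], by = "subject_id")
  slopes <- do.call(rbind, lapply(levels(factor(ser$tertile)), function(g) {
    d <- ser[ser$tertile == g, ]
    f <- stats::lm(change ~ visit_time, data = d)
    data.frame(tertile = g,
               slope = stats::coef(f)[["visit_time"]],
               se = summary(f)$coefficients["visit_time", "Std. Error"],
               n_subjects = length(unique(d$subject_id)),
               stringsAsFactors = FALSE)
  }))
  rownames(slopes) <- NULL
  list(series = ser[, c("subject_id", "visit_time", "change", "tertile")],
       slopes = slopes)
}
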