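#' Covariate-adjust memory scores by residualization
#'
#' Regresses the memory composite on the nuisance covariates (age, sex,
#' APOE4 allele count and the immune cell-type proportions) by ordinary
#' least squares and stores the residuals as the covariate-adjusted memory
#' score used as the outcome of the per-CpG moderation model. Cell-type
#' proportions are compositional (they sum to 1), so one column — the
#' granulocyte fraction by default — is dropped from the design to keep it
#' full rank.
#'
#' @param pheno Phenotype table with columns `memory`, `age`, `sex`, `apoe4`
#'   and the cell-proportion columns `B`, `NK`, `CD4T`, `CD8T`, `Mono`,
#'   `Gran`.
#' @param extra_covariates Optional character vector of additional pheno
#'   columns to adjust for (e.g. `"smoking"` for the sensitivity re-fit).
#' @param drop_cell Cell-proportion column excluded from the design.
#' @return `pheno` with `memory_resid` filled in.
#' @export
residualize_memory <- function(pheno, extra_covariates = NULL,
                               drop_cell = "Gran") {
  cells <- setdiff(c("B", "NK", "CD4T", "CD8T", "Mono", "Gran"), drop_cell)
  covars <- c("age", "sex", "apoe4", cells, extra_covariates)
  missing_cols <- setdiff(c("memory", covars), names(pheno))
  if (length(missing_cols))
    stop("pheno lacks column(s): ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(cbind(`(Intercept)` = 1, pheno[covars]))
  if (anyNA(X) || anyNA(pheno$memory))
    stop("covariates and memory must be complete (no missing values)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  pheno$memory_resid <- as.numeric(qr.resid(qrX, pheno$memory))
  pheno
}

#' Fit the per-CpG moderation model at one CpG
#'
#' Ordinary least squares of the covariate-adjusted memory score on z-scored
#' pTau181, the CpG's beta value, and their product:
#' \deqn{y = \alpha + \beta\,p + \tau M + \gamma\,M p + \varepsilon.}
#' The interaction coefficient \eqn{\gamma} is the moderation effect of
#' interest; its two-sided t test uses \eqn{n - 4} residual degrees of
#' freedom. A constant CpG or otherwise rank-deficient design yields a
#' failed fit (`ok = FALSE`, NA coefficients) rather than an error, so a
#' genome-wide scan can proceed past degenerate probes.
#'
#' @param m Beta values at one CpG, one per subject.
#' @param resid Covariate-adjusted memory scores.
#' @param ptau_z z-scored pTau181.
#' @return An object of class `cpg_fit`: coefficients (`alpha`, `beta_ptau`,
#'   `tau_dnam`, `gamma`), their standard errors, `t_gamma`, `p_gamma`,
#'   `df`, `sigma`, the 4x4 coefficient covariance `vcov`, and `ok`.
#' @export
fit_interaction_model <- function(m, resid, ptau_z) {
  n <- length(m)
  stopifnot(length(resid) == n, length(ptau_z) == n)
  if (n < 6) stop("need at least 6 subjects")
  out <- list(alpha = NA_real_, beta_ptau = NA_real_, tau_dnam = NA_real_,
              gamma = NA_real_, se_alpha = NA_real_, se_beta_ptau = NA_real_,
              se_tau_dnam = NA_real_, se_gamma = NA_real_,
              t_gamma = NA_real_, p_gamma = NA_real_,
              df = n - 4L, sigma = NA_real_, vcov = NULL, n = n, ok = FALSE)
  class(out) <- "cpg_fit"
  X <- cbind(1, ptau_z, m, m * ptau_z)
  qrX <- qr(X)
  if (stats::sd(m) == 0 || qrX$rank < 4L) return(out)
  cf <- unname(qr.coef(qrX, resid))
  res <- resid - X %*% cf
  rss <- sum(res^2)
  s2 <- rss / (n - 4)
  XtXi <- chol2inv(qr.R(qrX))
  V <- s2 * XtXi
  se <- sqrt(diag(V))
  out$alpha <- cf[1]; out$beta_ptau <- cf[2]
  out$tau_dnam <- cf[3]; out$gamma <- cf[4]
  out$se_alpha <- se[1]; out$se_beta_ptau <- se[2]
  out$se_tau_dnam <- se[3]; out$se_gamma <- se[4]
  out$t_gamma <- cf[4] / se[4]
  out$p_gamma <- 2 * stats::pt(abs(out$t_gamma), n - 4, lower.tail = FALSE)
  out$sigma <- sqrt(s2)
  dimnames(V) <- list(c("alpha", "beta_ptau", "tau_dnam", "gamma"),
                      c("alpha", "beta_ptau", "tau_dnam", "gamma"))
  out$vcov <- V
  out$ok <- TRUE
  out
}

#' @export
print.cpg_fit <- function(x, ...) {
  if (!x$ok) { cat("cpg_fit: failed (degenerate design)\n"); return(invisible(x)) }
  cat(sprintf(
    "cpg_fit: gamma = %.4g (SE %.3g, p = %.3g), beta_ptau = %.4g, df = %d\n",
    x$gamma, x$se_gamma, x$p_gamma, x$beta_ptau, x$df))
  invisible(x)
}

#' Genome-wide scan of the moderation model
#'
#' Fits [fit_interaction_model()] at every CpG of a beta matrix against the
#' covariate-adjusted memory score, returning one row per CpG together with
#' the beta-value interquartile range used by the variability filter.
#'
#' @param betas A [beta_matrix()] whose subject columns match
#'   `pheno$subject_id` exactly (same order).
#' @param pheno Phenotype table with `memory_resid` filled (see
#'   [residualize_memory()]) and `ptau_z`.
#' @return A data.frame of class `ewas_result`: `cpg_id`, `chrom`, `pos`,
#'   per-CpG coefficients and standard errors (`estimate`/`std_err`/`t`/
#'   `p_value` refer to the interaction term), `cov_beta_gamma`, `df`,
#'   `sigma`, `iqr`, and `fit_ok`. Empirical-null-corrected columns and
#'   `fdr_q` are appended by [bacon_adjust_ewas()].
#' @export
run_ewas <- function(betas, pheno) {
  stopifnot(inherits(betas, "beta_matrix"))
  if (!identical(colnames(betas$beta), pheno$subject_id))
    stop("subject columns of betas do not match pheno$subject_id")
  if (anyNA(pheno$memory_resid))
    stop("memory_resid missing; run residualize_memory() first")
  y <- pheno$memory_resid
  pz <- pheno$ptau_z
  k <- nrow(betas$beta)
  cols <- c("alpha", "beta_ptau", "tau_dnam", "gamma", "se_alpha",
            "se_beta_ptau", "se_tau_dnam", "se_gamma", "t_gamma", "p_gamma",
            "sigma", "cov_beta_gamma")
  M <- matrix(NA_real_, k, length(cols), dimnames = list(NULL, cols))
  ok <- logical(k)
  for (i in seq_len(k)) {
    f <- fit_interaction_model(betas$beta[i, ], y, pz)
    if (f$ok) {
      M[i, ] <- c(f$alpha, f$beta_ptau, f$tau_dnam, f$gamma, f$se_alpha,
                  f$se_beta_ptau, f$se_tau_dnam, f$se_gamma, f$t_gamma,
                  f$p_gamma, f$sigma, f$vcov["beta_ptau", "gamma"])
      ok[i] <- TRUE
    }
  }
  iqr <- apply(betas$beta, 1, function(v)
    diff(stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)))
  out <- data.frame(cpg_id = betas$cpg_id, chrom = betas$chrom,
                    pos = betas$pos,
                    estimate = M[, "gamma"], std_err = M[, "se_gamma"],
                    t = M[, "t_gamma"], p_value = M[, "p_gamma"],
                    alpha = M[, "alpha"],
                    beta_ptau = M[, "beta_ptau"],
                    se_beta_ptau = M[, "se_beta_ptau"],
                    tau_dnam = M[, "tau_dnam"],
                    se_tau_dnam = M[, "se_tau_dnam"],
                    cov_beta_gamma = M[, "cov_beta_gamma"],
                    df = length(y) - 4L, sigma = M[, "sigma"],
                    iqr = iqr, fit_ok = ok,
                    stringsAsFactors = FALSE)
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Low-variability CpG filter
#'
#' Computes the beta-value interquartile range of every CpG (type-7,
#' linear-interpolation quantiles) and keeps those exceeding the threshold.
#' Near-constant probes carry no usable moderation signal and inflate the
#' multiple-testing burden.
#'
#' @param betas A [beta_matrix()] with at least 4 subjects.
#' @param threshold Minimum IQR (strict inequality); default 0.02.
#' @return A list with logical `kept` and numeric `iqr`, both named by CpG.
#' @export
iqr_filter <- function(betas, threshold = 0.02) {
  stopifnot(inherits(betas, "beta_matrix"))
  if (ncol(betas$beta) < 4) stop("need at least 4 subjects")
  iqr <- apply(betas$beta, 1, function(v)
    diff(stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)))
  names(iqr) <- betas$cpg_id
  list(kept = iqr > threshold, iqr = iqr)
}

#' PCA-based sample outlier filter
#'
#' Runs principal component analysis with samples as observations on
#' centered, unit-variance CpG features and removes any sample whose PC1 or
#' PC2 score lies more than `sd_limit` standard deviations from that
#' component's mean (two-sided).
#'
#' @param betas A [beta_matrix()] with at least 3 samples.
#' @param sd_limit Number of SDs defining the fence (default 3).
#' @return A list with logical `kept` (named by subject) and the `scores`
#'   matrix of the first two components.
#' @export
pca_outlier_filter <- function(betas, sd_limit = 3) {
  stopifnot(inherits(betas, "beta_matrix"))
  X <- t(betas$beta)
  if (nrow(X) < 3) stop("need at least 3 samples")
  keep_feat <- apply(X, 2, stats::sd) > 0
  Xs <- scale(X[, keep_feat, drop = FALSE])
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE, rank. = 2)
  scores <- pc$x[, 1:2, drop = FALSE]
  z <- scale(scores)
  kept <- apply(abs(z) <= sd_limit, 1, all)
  names(kept) <- rownames(X)
  list(kept = kept, scores = scores)
}

#' DNAm-conditional pTau slope with confidence interval
#'
#' Evaluates the pTau-memory slope at a fixed methylation level,
#' \eqn{\beta + \gamma m}, with its t-based confidence interval from the
#' stored coefficient covariance:
#' \eqn{\mathrm{var} = \mathrm{var}(\hat\beta) + m^2 \mathrm{var}(\hat\gamma)
#' + 2 m\,\mathrm{cov}(\hat\beta, \hat\gamma)}. Typical use fixes `m_value`
#' at the 25th and 75th percentiles of the CpG's beta values to display the
#' moderation pattern.
#'
#' @param fit A successful [fit_interaction_model()] result.
#' @param m_value Methylation level(s) at which to evaluate the slope.
#' @param level Confidence level (default 0.95).
#' @return A data.frame with `m`, `slope`, `ci_low`, `ci_high`.
#' @export
slope_at_dnam <- function(fit, m_value, level = 0.95) {
  stopifnot(inherits(fit, "cpg_fit"))
  if (!fit$ok) stop("cannot evaluate slope for a failed fit")
  vb <- fit$vcov["beta_ptau", "beta_ptau"]
  vg <- fit$vcov["gamma", "gamma"]
  cv <- fit$vcov["beta_ptau", "gamma"]
  slope <- fit$beta_ptau + fit$gamma * m_value
  se <- sqrt(vb + m_value^2 * vg + 2 * m_value * cv)
  tq <- stats::qt(1 - (1 - level) / 2, fit$df)
  data.frame(m = m_value, slope = slope,
             ci_low = slope - tq * se, ci_high = slope + tq * se)
}
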