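#' Blood-brain cross-tissue methylation correlation
#'
#' Spearman rank correlation between matched blood and brain methylation
#' profiles at each CpG. In the unadjusted mode the beta values are
#' correlated directly; in the adjusted mode each tissue's beta values are
#' first regressed (OLS) on that tissue's covariates — typically cell or
#' neuron proportions, batch, age and sex — and the residuals are
#' correlated, removing confounding shared with the covariates. Ties use
#' average ranks; p-values come from the t approximation, switching to the
#' exact null distribution for fewer than 10 pairs.
#'
#' @param brain_m,blood_m Numeric matrices (CpG x sample) with identical
#'   dimensions and matched sample order; row names are CpG ids.
#' @param brain_covars,blood_covars Per-tissue covariate data.frames (one
#'   row per sample), required when `adjusted = TRUE`.
#' @param adjusted Correlate covariate residuals instead of raw betas.
#' @return A data.frame with `cpg_id`, `rho`, `p`, `fdr_q` (BH across
#'   CpGs).
#' @export
brain_blood_correlation <- function(brain_m, blood_m, brain_covars = NULL,
                                    blood_covars = NULL, adjusted = FALSE) {
  brain_m <- as.matrix(brain_m); blood_m <- as.matrix(blood_m)
  if (!all(dim(brain_m) == dim(blood_m)))
    stop("brain and blood matrices must have matching dimensions")
  n <- ncol(brain_m)
  if (n < 5) stop("need at least 5 matched sample pairs")
  if (adjusted) {
    if (is.null(brain_covars) || is.null(blood_covars))
      stop("adjusted analysis requires covariates for both tissues")
    tissue_resid <- function(m, covars) {
      X <- stats::model.matrix(~ ., data = as.data.frame(covars))
      if (anyNA(X)) stop("covariates must be complete")
      t(qr.resid(qr(X), t(m)))
    }
    brain_m <- tissue_resid(brain_m, brain_covars)
    blood_m <- tissue_resid(blood_m, blood_covars)
  }
  rows <- lapply(seq_len(nrow(brain_m)), function(i) {
    ct <- suppressWarnings(stats::cor.test(brain_m[i, ], blood_m[i, ],
                                           method = "spearman",
                                           exact = n < 10))
    data.frame(cpg_id = rownames(brain_m)[i] %||% as.character(i),
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
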