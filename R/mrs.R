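#' Methylation Reserve Score
#'
#' For each subject, evaluates the DNAm-conditional pTau slope at every
#' selected CpG, \eqn{\beta_j + \gamma_j M_{ij}}, and averages across CpGs
#' to obtain the raw score; lower raw values indicate a more harmful pTau
#' effect on memory (less reserve), higher values indicate attenuation. The
#' raw score is then z-scored (sample SD) and split into tertiles. The
#' selected CpGs are typically the suggestive individual CpGs plus all CpGs
#' inside reported DMRs.
#'
#' By default the raw per-CpG OLS estimates of \eqn{\beta} and \eqn{\gamma}
#' feed the score, since the score formula is defined on the moderation
#' model directly; `use_corrected = TRUE` switches to the empirical-null
#' corrected interaction estimates.
#'
#' @param betas_subset A [beta_matrix()] restricted to the selected CpGs.
#' @param fits An `ewas_result` (or any data.frame) carrying `cpg_id`,
#'   `beta_ptau` and `estimate` (+ `estimate_bacon` when `use_corrected`)
#'   for every selected CpG.
#' @param use_corrected Use corrected interaction estimates (default FALSE).
#' @return A data.frame of class `mrs_result`: `subject_id`, `mrs_raw`,
#'   `mrs_z`, `tertile` (factor low/mid/high).
#' @export
compute_mrs <- function(betas_subset, fits, use_corrected = FALSE) {
  stopifnot(inherits(betas_subset, "beta_matrix"))
  if (ncol(betas_subset$beta) < 2) stop("need at least 2 subjects")
  idx <- match(betas_subset$cpg_id, fits$cpg_id)
  if (anyNA(idx))
    stop("no fit for CpG(s): ",
         paste(betas_subset$cpg_id[is.na(idx)], collapse = ", "))
  gamma <- if (use_corrected) fits$estimate_bacon[idx] else fits$estimate[idx]
  beta_p <- fits$beta_ptau[idx]
  if (anyNA(gamma) || anyNA(beta_p))
    stop("selected CpGs include failed fits (NA coefficients)")
  ## per-subject mean over CpGs of beta_ptau_j + gamma_j * M_j
  raw <- as.numeric(crossprod(betas_subset$beta, gamma) +
                      sum(beta_p)) / length(gamma)
  if (stats::sd(raw) == 0)
    stop("MRS has zero variance across subjects; z-score undefined")
  out <- data.frame(subject_id = colnames(betas_subset$beta),
                    mrs_raw = raw,
                    mrs_z = (raw - mean(raw)) / stats::sd(raw),
                    stringsAsFactors = FALSE)
  out$tertile <- if (nrow(out) >= 3) tertile_groups(out$mrs_z) else
    factor(rep(NA_character_, nrow(out)), levels = c("low", "mid", "high"))
  class(out) <- c("mrs_result", "data.frame")
  out
}

#' Tertile grouping of a score
#'
#' Splits subjects into low/mid/high groups by increasing score. Group
#' sizes are as equal as possible (they differ by at most 1, extra members
#' going to the lower groups first); ties are broken by stable input order.
#'
#' @param x Numeric scores (at least 3).
#' @return A factor with levels `low`, `mid`, `high`, aligned with `x`.
#' @examples
#' table(tertile_groups(1:10))
#' @export
tertile_groups <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 subjects for tertiles")
  base <- n %/% 3
  rem <- n %% 3
  sizes <- base + c(rem >= 1, rem >= 2, 0)
  labels <- rep(c("low", "mid", "high"), times = sizes)
  out <- character(n)
  out[order(x)] <- labels        # order() is stable for ties
  factor(out, levels = c("low", "mid", "high"))
}
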