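#' Simulate a cross-sectional cohort with known moderation structure
#'
#' Generates a methylation beta matrix, a subject phenotype table and a
#' ground-truth table under the moderation model used by the analysis: the
#' covariate-adjusted memory score depends on z-scored CSF pTau181, on DNAm
#' at spiked CpGs, and on their product. CSF pTau181 is drawn lognormal with
#' moments matched to the study sample (mean 46.46, SD 27.32 pg/mL) and then
#' z-scored. Betas are logit-normal; probes inside spiked regions share an
#' AR(1) latent process so neighbouring probes are correlated, and a
#' configurable fraction of background CpGs is generated near-constant to
#' exercise the low-variability filter.
#'
#' @param config A [sim_config()].
#' @return A list with elements `betas` (a [beta_matrix()]), `pheno`
#'   (data.frame, one row per subject) and `truth` (list with per-CpG
#'   effects, per-subject true reserve, and spiked region intervals).
#' @examples
#' sim <- simulate_cohort(sim_config(n_subjects = 40, n_cpgs = 100, seed = 3))
#' dim(sim$betas)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects

  pheno <- simulate_pheno(n)

  n_dmr_probes <- sum(vapply(config$dmr_specs, function(s) s$n_probes, 0))
  n_bg <- config$n_cpgs - n_dmr_probes

  ## background CpGs: round-robin chromosomes with lognormal inter-probe
  ## gaps, so close probe pairs exist at the few-hundred-bp scale as on a
  ## real array (this is what the distance-binned autocorrelation sees)
  chrom_bg <- paste0("chr", rep_len(1:22, n_bg))
  pos_bg <- integer(n_bg)
  for (ch in unique(chrom_bg)) {
    idx <- which(chrom_bg == ch)
    gaps <- pmax(round(stats::rlnorm(length(idx), log(1500), 1.3)), 50)
    pos_bg[idx] <- 1000013L + cumsum(gaps)
  }

  n_low <- floor(config$frac_low_iqr * n_bg)
  slots <- sample.int(n_bg)                    # random CpG roles
  low_idx <- slots[seq_len(n_low)]
  sig_idx <- slots[n_low + seq_len(config$n_signal_cpgs)]

  mu_bg <- stats::runif(n_bg, -2.5, 2.5)
  sd_bg <- stats::runif(n_bg, 0.25, 0.6)
  ## near-constant CpGs: logit SD small enough that the beta-scale IQR stays
  ## below 0.02 (IQR <= 0.25 * 1.349 * sd on the steepest part of the logistic)
  sd_bg[low_idx] <- stats::runif(n_low, 0.02, 0.04)
  beta_bg <- stats::plogis(mu_bg + sd_bg * matrix(stats::rnorm(n_bg * n), n_bg, n))

  gamma_bg <- numeric(n_bg)
  tau_bg <- numeric(n_bg)
  gamma_bg[sig_idx] <- config$gamma_range
  tau_bg[sig_idx] <- config$tau_signal

  cpg_id <- sprintf("cg%08d", seq_len(n_bg))
  chrom <- chrom_bg; pos <- pos_bg
  beta <- beta_bg; gamma <- gamma_bg; tau <- tau_bg
  dmr_truth <- NULL

  k0 <- n_bg
  for (spec in config$dmr_specs) {
    p <- spec$n_probes
    reg_pos <- spec$start_pos + spec$probe_spacing * (seq_len(p) - 1L)
    ## region methylation level on the logit scale; configurable so a
    ## fixture can pin, e.g., a mid-methylated (maximally variable) region
    mu_r <- if (!is.null(spec$mu)) spec$mu else stats::runif(1, -1.5, 1.5)
    z <- matrix(stats::rnorm(p * n), p, n)
    if (p > 1 && config$ar_rho > 0) {
      for (j in 2:p)
        z[j, ] <- config$ar_rho * z[j - 1, ] +
          sqrt(1 - config$ar_rho^2) * z[j, ]
    }
    beta_r <- stats::plogis(mu_r + 0.4 * z)
    beta <- rbind(beta, beta_r)
    cpg_id <- c(cpg_id, sprintf("cg%08d", k0 + seq_len(p)))
    chrom <- c(chrom, rep(spec$chrom, p))
    pos <- c(pos, reg_pos)
    gamma <- c(gamma, rep(spec$sign * spec$gamma_effect, p))
    tau <- c(tau, rep(0, p))
    dmr_truth <- rbind(dmr_truth,
                       data.frame(chrom = spec$chrom,
                                  start = reg_pos[1],
                                  end = reg_pos[p] + 1L,
                                  n_probes = p))
    k0 <- k0 + p
  }

  ## memory score: covariates + main pTau + spiked DNAm main/interaction terms
  eff <- config$covariate_effects
  pz <- pheno$ptau_z
  lin <- eff[["age"]] * (pheno$age - mean(pheno$age)) +
    eff[["sex"]] * pheno$sex + eff[["apoe4"]] * pheno$apoe4 +
    eff[["education"]] * (pheno$education - mean(pheno$education))
  ## spiked effects enter centered on the cohort-average methylation, so
  ## beta_ptau is the pTau slope at average DNAm (the interpretable scale)
  ## rather than at the unobservable M = 0
  sig <- which(gamma != 0 | tau != 0)
  if (length(sig)) {
    M <- beta[sig, , drop = FALSE] - rowMeans(beta[sig, , drop = FALSE])
    lin <- lin + as.numeric(crossprod(M, tau[sig])) +
      pz * as.numeric(crossprod(M, gamma[sig]))
  }
  pheno$memory <- lin + config$beta_ptau * pz +
    stats::rnorm(n, 0, config$noise_sd)
  pheno$memory_resid <- NA_real_

  ## true per-subject reserve: DNAm-conditional pTau slope averaged over the
  ## spiked CpGs (the generative analogue of the MRS), z-scored
  sig_g <- which(gamma != 0)
  if (length(sig_g)) {
    raw <- config$beta_ptau +
      as.numeric(crossprod(beta[sig_g, , drop = FALSE], gamma[sig_g])) /
      length(sig_g)
    reserve <- zscore_or_zero(raw)
  } else {
    reserve <- rep(0, n)
  }

  colnames(beta) <- pheno$subject_id
  betas <- beta_matrix(beta, cpg_id, chrom, pos)
  truth_cpg <- data.frame(cpg_id = cpg_id, gamma = gamma, tau = tau)
  truth_cpg <- truth_cpg[match(betas$cpg_id, truth_cpg$cpg_id), ]
  rownames(truth_cpg) <- NULL
  truth <- list(cpg = truth_cpg,
                reserve = data.frame(subject_id = pheno$subject_id,
                                     reserve = reserve),
                dmrs = dmr_truth)
  list(betas = betas, pheno = pheno, truth = truth)
}

simulate_pheno <- function(n) {
  subject_id <- sprintf("S%04d", seq_len(n))
  age <- stats::rnorm(n, 74.67, 7.51)
  sex <- stats::rbinom(n, 1, 0.4457)              # 1 = female, male reference
  apoe4 <- sample(0:2, n, replace = TRUE, prob = c(0.48, 0.42, 0.10))
  education <- pmax(round(stats::rnorm(n, 16.21, 2.78)), 6)
  smoking <- stats::rbinom(n, 1, 0.4348)
  ## immune cell proportions: Dirichlet around typical whole-blood fractions;
  ## granulocyte = neutrophils + eosinophils combined
  base <- c(B = 0.06, NK = 0.06, CD4T = 0.16, CD8T = 0.08,
            Mono = 0.09, Gran = 0.55)
  g <- matrix(stats::rgamma(n * 6, shape = rep(base * 200, each = n)), n, 6)
  props <- g / rowSums(g)
  colnames(props) <- names(base)
  ## lognormal pTau181 with moments matched to mean 46.46 / SD 27.32 pg/mL
  cv2 <- (27.32 / 46.46)^2
  s2 <- log(1 + cv2)
  ptau_raw <- stats::rlnorm(n, log(46.46) - s2 / 2, sqrt(s2))
  data.frame(subject_id = subject_id, age = age, sex = sex, apoe4 = apoe4,
             education = education, smoking = smoking, props,
             ptau_raw = ptau_raw,
             ptau_z = zscore_or_zero(ptau_raw),
             memory = NA_real_, memory_resid = NA_real_,
             stringsAsFactors = FALSE)
}

#' Simulate longitudinal memory trajectories
#'
#' Generates repeated memory measurements under a random-intercept model
#' whose yearly slope depends on baseline pTau and on the subject's true
#' reserve: \eqn{y_{ij} = \mu_i + (s_0 + s_p p_i + s_r r_i) t_{ij} + b_i +
#' \varepsilon_{ij}}, with \eqn{b_i \sim N(0, \sigma_b^2)}. The baseline mean
#' \eqn{\mu_i} carries the configured covariate, pTau, reserve and
#' pTau-by-reserve effects. Every subject has a baseline row at time 0; a
#' configurable fraction receives one or more follow-up visits at fixed
#' spacing.
#'
#' @param pheno Phenotype table from [simulate_cohort()] (needs `ptau_z`).
#' @param truth Truth table from [simulate_cohort()] (needs `reserve`).
#' @param config The [sim_config()] used for the cohort.
#' @param seed Optional integer seed; defaults to `config$seed + 1`.
#' @return A data.frame with columns `subject_id`, `visit_time` (years since
#'   baseline) and `memory`.
#' @export
simulate_longitudinal <- function(pheno, truth, config, seed = NULL) {
  validate_sim_config(config)
  if (is.null(truth$reserve) || !"reserve" %in% names(truth$reserve))
    stop("truth table lacks the per-subject reserve covariate")
  res <- truth$reserve$reserve[match(pheno$subject_id,
                                     truth$reserve$subject_id)]
  if (anyNA(res)) stop("truth reserve does not cover all subjects")
  set.seed(if (is.null(seed)) config$seed + 1L else as.integer(seed))
  n <- nrow(pheno)
  eff <- config$covariate_effects
  pz <- pheno$ptau_z
  mu <- eff[["age"]] * (pheno$age - mean(pheno$age)) +
    eff[["sex"]] * pheno$sex + eff[["apoe4"]] * pheno$apoe4 +
    eff[["education"]] * (pheno$education - mean(pheno$education)) +
    config$base_ptau * pz + config$base_mrs * res +
    config$base_mrs_ptau * pz * res
  slope <- config$slope_base + config$slope_ptau * pz + config$slope_mrs * res
  b <- stats::rnorm(n, 0, config$rand_intercept_sd)

  has_fu <- stats::rbinom(n, 1, config$followup_frac) == 1
  max_fu <- max(config$n_visits - 1L, 1L)
  n_fu <- ifelse(has_fu & config$n_visits > 1,
                 if (identical(config$visit_schedule, "fixed")) max_fu
                 else sample.int(max_fu, n, replace = TRUE),
                 0L)
  rows <- lapply(seq_len(n), function(i) {
    t <- config$visit_spacing_years * (0:n_fu[i])
    data.frame(subject_id = pheno$subject_id[i], visit_time = t,
               memory = mu[i] + slope[i] * t + b[i] +
                 stats::rnorm(length(t), 0, config$long_noise_sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## z-score with the sample SD; a zero-variance vector maps to zeros rather
## than NaN
zscore_or_zero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
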