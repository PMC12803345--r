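#' Simulation configuration for synthetic memory-reserve cohorts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()] and [simulate_longitudinal()]. Defaults emulate the
#' amyloid-positive MCI study sample: 92 subjects, age 74.67 (SD 7.51) years,
#' 44.6% female, 52% APOE4 carriers, education 16.21 (SD 2.78) years, 43%
#' ever-smokers, and CSF pTau181 with mean 46.46 and SD 27.32 pg/mL.
#'
#' Methylation beta values are generated on the logit scale (normal marginals,
#' AR(1) correlation within spiked regions) and mapped back through the
#' inverse logit, which keeps them strictly inside (0, 1) while making the
#' within-region correlation tunable. The covariate-adjusted memory score is
#' generated from the moderation model
#' \deqn{y_i = x_i'\delta + \beta\,p_i + \sum_j (\tau_j + \gamma_j p_i) M_{ij} + \varepsilon_i,}
#' where \eqn{p_i} is z-scored pTau181 and \eqn{M_{ij}} the beta value of CpG
#' \eqn{j}, so the interaction coefficients \eqn{\gamma_j} are nonzero exactly
#' at the spiked CpGs and region probes recorded in the truth table.
#'
#' @param n_subjects Number of subjects (default 92).
#' @param n_cpgs Number of background CpGs before spiked regions are added.
#' @param n_signal_cpgs Number of isolated CpGs carrying a true interaction.
#' @param dmr_specs List of spiked-region descriptors; each element is a list
#'   with fields `chrom`, `start_pos`, `n_probes`, `probe_spacing` (bp),
#'   `gamma_effect` (>= 0) and `sign` (+1 or -1).
#' @param gamma_range Interaction effect at isolated signal CpGs, in memory
#'   units per SD of pTau per unit beta value (signed).
#' @param beta_ptau Main pTau effect on adjusted memory (memory units per SD).
#' @param tau_signal DNAm main effect at signal CpGs (default 0).
#' @param covariate_effects Named vector of effects for `age`, `sex`,
#'   `apoe4`, `education` on the raw memory score.
#' @param noise_sd Residual SD of the cross-sectional memory score.
#' @param ar_rho AR(1) correlation of adjacent probes within spiked regions,
#'   in [0, 1).
#' @param frac_low_iqr Fraction of background CpGs generated near-constant
#'   (beta-scale IQR below 0.02).
#' @param n_visits Maximum number of visits (baseline included).
#' @param visit_spacing_years Years between consecutive visits.
#' @param visit_schedule `"random"` (each follow-up subject gets a uniform
#'   1 to `n_visits - 1` follow-ups) or `"fixed"` (every follow-up subject
#'   completes all `n_visits - 1` follow-ups).
#' @param followup_frac Fraction of subjects with at least one follow-up.
#' @param slope_base Yearly memory slope at mean MRS and mean pTau.
#' @param slope_ptau Change in yearly slope per SD of baseline pTau.
#' @param slope_mrs Change in yearly slope per SD of the true reserve score.
#' @param base_ptau,base_mrs,base_mrs_ptau Baseline (time 0) effects of pTau,
#'   reserve, and their product on longitudinal memory.
#' @param rand_intercept_sd SD of the subject random intercept.
#' @param long_noise_sd Visit-level residual SD of longitudinal memory.
#' @param seed Integer seed; all randomness in the generators flows from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_subjects = 50, n_cpgs = 200, seed = 7)
#' cfg$n_subjects
#' @export
sim_config <- function(n_subjects = 92L,
                       n_cpgs = 2000L,
                       n_signal_cpgs = 0L,
                       dmr_specs = list(),
                       gamma_range = 0.06,
                       beta_ptau = -0.2,
                       tau_signal = 0,
                       covariate_effects = c(age = -0.03, sex = 0.1,
                                             apoe4 = -0.3, education = 0.04),
                       noise_sd = 0.5,
                       ar_rho = 0.6,
                       frac_low_iqr = 0.1,
                       n_visits = 6L,
                       visit_spacing_years = 1,
                       visit_schedule = c("random", "fixed"),
                       followup_frac = 0.95,
                       slope_base = -0.050,
                       slope_ptau = -0.026,
                       slope_mrs = 0.034,
                       base_ptau = -0.138,
                       base_mrs = -0.135,
                       base_mrs_ptau = 0.217,
                       rand_intercept_sd = 0.5,
                       long_noise_sd = 0.15,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_cpgs = as.integer(n_cpgs),
              n_signal_cpgs = as.integer(n_signal_cpgs),
              dmr_specs = dmr_specs,
              gamma_range = gamma_range,
              beta_ptau = beta_ptau,
              tau_signal = tau_signal,
              covariate_effects = covariate_effects,
              noise_sd = noise_sd,
              ar_rho = ar_rho,
              frac_low_iqr = frac_low_iqr,
              n_visits = as.integer(n_visits),
              visit_spacing_years = visit_spacing_years,
              visit_schedule = match.arg(visit_schedule),
              followup_frac = followup_frac,
              slope_base = slope_base,
              slope_ptau = slope_ptau,
              slope_mrs = slope_mrs,
              base_ptau = base_ptau,
              base_mrs = base_mrs,
              base_mrs_ptau = base_mrs_ptau,
              rand_intercept_sd = rand_intercept_sd,
              long_noise_sd = long_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L, cfg$n_cpgs >= 1L, cfg$n_signal_cpgs >= 0L,
            cfg$n_visits >= 1L)
  if (cfg$ar_rho < 0 || cfg$ar_rho >= 1)
    stop("ar_rho must lie in [0, 1)")
  if (cfg$frac_low_iqr < 0 || cfg$frac_low_iqr > 1)
    stop("frac_low_iqr must lie in [0, 1]")
  if (cfg$visit_spacing_years <= 0)
    stop("visit_spacing_years must be positive")
  if (cfg$followup_frac < 0 || cfg$followup_frac > 1)
    stop("followup_frac must lie in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$rand_intercept_sd < 0 || cfg$long_noise_sd < 0)
    stop("noise SDs must be nonnegative")
  for (spec in cfg$dmr_specs) {
    need <- c("chrom", "start_pos", "n_probes", "probe_spacing",
              "gamma_effect", "sign")
    if (!all(need %in% names(spec)))
      stop("each dmr_spec needs fields: ", paste(need, collapse = ", "))
    if (spec$n_probes < 1L || spec$probe_spacing < 1)
      stop("dmr_spec n_probes and probe_spacing must be >= 1")
    if (!spec$sign %in% c(-1, 1)) stop("dmr_spec sign must be +1 or -1")
  }
  n_dmr_probes <- sum(vapply(cfg$dmr_specs, function(s) s$n_probes, 0))
  if (cfg$n_signal_cpgs + n_dmr_probes > cfg$n_cpgs)
    stop("invalid config: n_signal_cpgs + DMR probes exceed n_cpgs")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_subjects, "subjects,", x$n_cpgs, "CpGs,",
      x$n_signal_cpgs, "signal CpGs,", length(x$dmr_specs),
      "spiked region(s), seed", x$seed, "\n")
  invisible(x)
}
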