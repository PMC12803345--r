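test_that("simulated cohorts match the target demographic and biomarker distributions", {
  stats <- t(sapply(1:30, function(r) {
    ph <- simulate_cohort(sim_config(n_cpgs = 20, seed = 100 + r))$pheno
    c(age = mean(ph$age), age_sd = sd(ph$age), female = mean(ph$sex),
      carrier = mean(ph$apoe4 > 0), edu = mean(ph$education),
      smoke = mean(ph$smoking), ptau = mean(ph$ptau_raw),
      ptau_sd = sd(ph$ptau_raw))
  }))
  m <- colMeans(stats)
  expect_lt(abs(m[["age"]] - 74.67), 0.5)
  expect_lt(abs(m[["age_sd"]] - 7.51), 0.6)
  expect_lt(abs(m[["female"]] - 0.4457), 0.04)
  expect_lt(abs(m[["carrier"]] - 0.5217), 0.04)
  expect_lt(abs(m[["edu"]] - 16.21), 0.3)
  expect_lt(abs(m[["smoke"]] - 0.4348), 0.04)
  expect_lt(abs(m[["ptau"]] - 46.46), 1.5)
  expect_lt(abs(m[["ptau_sd"]] - 27.32), 3)
})

test_that("generated data honor the structural invariants", {
  cfg <- sim_config(n_subjects = 200, n_cpgs = 300, n_signal_cpgs = 3,
                    frac_low_iqr = 0.2, seed = 7)
  sim <- simulate_cohort(cfg)
  ph <- sim$pheno
  expect_true(all(sim$betas$beta > 0 & sim$betas$beta < 1))
  expect_false(anyDuplicated(ph$subject_id) > 0)
  cells <- as.matrix(ph[, c("B", "NK", "CD4T", "CD8T", "Mono", "Gran")])
  expect_true(all(cells >= 0 & cells <= 1))
  expect_equal(rowSums(cells), rep(1, nrow(ph)), tolerance = 1e-8)
  expect_lt(abs(mean(ph$ptau_z)), 1e-6)
  expect_lt(abs(sd(ph$ptau_z) - 1), 1e-6)
  expect_true(all(ph$ptau_raw > 0))
  # interaction truth is nonzero exactly at the spiked CpGs
  expect_identical(sum(sim$truth$cpg$gamma != 0), 3L)
  # the near-constant fraction really falls under the variability threshold
  iqr <- iqr_filter(sim$betas)$iqr
  expect_gte(sum(iqr < 0.02), 0.8 * floor(0.2 * 300))
  # positions sorted within chromosome
  for (ch in unique(sim$betas$chrom))
    expect_false(is.unsorted(sim$betas$pos[sim$betas$chrom == ch],
                             strictly = TRUE))
  # oversubscribed signal is rejected
  expect_error(sim_config(n_cpgs = 5, n_signal_cpgs = 10), "invalid config")
})

test_that("a null configuration carries no pTau-memory association on average", {
  slopes <- sapply(1:60, function(r) {
    cfg <- sim_config(n_cpgs = 5, gamma_range = 0, beta_ptau = 0,
                      covariate_effects = c(age = 0, sex = 0, apoe4 = 0,
                                            education = 0),
                      seed = 300 + r)
    ph <- simulate_cohort(cfg)$pheno
    coef(lm(memory ~ ptau_z, data = ph))[["ptau_z"]]
  })
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("a spiked interaction effect is recovered without bias", {
  # single-seed recovery through the genome-wide scan
  cfg <- sim_config(n_subjects = 500, n_cpgs = 40, n_signal_cpgs = 1,
                    gamma_range = 0.06, noise_sd = 0.1, seed = 11)
  sim <- simulate_cohort(cfg)
  ew <- run_ewas(sim$betas, residualize_memory(sim$pheno))
  spiked <- sim$truth$cpg$cpg_id[sim$truth$cpg$gamma != 0]
  row <- ew[ew$cpg_id == spiked, ]
  expect_lt(abs(row$estimate - 0.06), 2 * row$std_err)

  # unbiasedness: mean deviation of gamma-hat from truth shrinks with
  # replication (150 cohorts at n = 500)
  devs <- sapply(1:150, function(r) {
    cfg <- sim_config(n_subjects = 500, n_cpgs = 4, n_signal_cpgs = 1,
                      gamma_range = 0.06, noise_sd = 0.1, seed = 5000 + r)
    sim <- simulate_cohort(cfg)
    ph <- residualize_memory(sim$pheno)
    spiked <- sim$truth$cpg$cpg_id[sim$truth$cpg$gamma != 0]
    i <- match(spiked, sim$betas$cpg_id)
    f <- fit_interaction_model(sim$betas$beta[i, ], ph$memory_resid,
                               ph$ptau_z)
    f$gamma - 0.06
  })
  expect_lt(abs(mean(devs)), 3 * sd(devs) / sqrt(length(devs)))
})

test_that("region probes correlate at the configured autoregressive level", {
  cfg <- sim_config(n_subjects = 500, n_cpgs = 60, ar_rho = 0.6,
                    dmr_specs = list(list(chrom = "chr3", start_pos = 2e6,
                                          n_probes = 10, probe_spacing = 100,
                                          gamma_effect = 0, sign = 1)),
                    seed = 21)
  sim <- simulate_cohort(cfg)
  idx <- which(sim$betas$chrom == "chr3" & sim$betas$pos >= 2e6 &
                 sim$betas$pos < 2e6 + 1000)
  expect_length(idx, 10)
  adj <- sapply(seq_len(9), function(j)
    cor(sim$betas$beta[idx[j], ], sim$betas$beta[idx[j + 1], ]))
  expect_lt(abs(mean(adj) - 0.6), 0.1)
})

test_that("longitudinal trajectories honor schedule, baselines, and degenerate settings", {
  cfg <- sim_config(n_cpgs = 5, n_signal_cpgs = 1, gamma_range = 0.5,
                    slope_base = 0, slope_ptau = 0, slope_mrs = 0,
                    base_ptau = 0, base_mrs = 0, base_mrs_ptau = 0,
                    covariate_effects = c(age = 0, sex = 0, apoe4 = 0,
                                          education = 0),
                    rand_intercept_sd = 0, long_noise_sd = 0,
                    followup_frac = 1, seed = 31)
  sim <- simulate_cohort(cfg)
  long <- simulate_longitudinal(sim$pheno, sim$truth, cfg)
  # flat trajectories when every slope and noise component is off
  spread <- tapply(long$memory, long$subject_id, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
  # every subject has a baseline row and strictly increasing times
  base <- tapply(long$visit_time, long$subject_id, min)
  expect_true(all(base == 0))
  inc <- tapply(long$visit_time, long$subject_id,
                function(v) all(diff(v) > 0))
  expect_true(all(inc))

  # fixed schedule gives every follow-up subject the full visit count
  cfg2 <- sim_config(n_cpgs = 5, n_signal_cpgs = 1, n_visits = 5,
                     visit_schedule = "fixed", followup_frac = 1, seed = 32)
  sim2 <- simulate_cohort(cfg2)
  long2 <- simulate_longitudinal(sim2$pheno, sim2$truth, cfg2)
  expect_true(all(table(long2$subject_id) == 5))

  # ~95% follow-up reproduces the 88-of-92 retention pattern on average
  cfg$followup_frac <- 0.95
  n_fu <- sapply(1:40, function(r) {
    l <- simulate_longitudinal(sim$pheno, sim$truth, cfg, seed = 600 + r)
    sum(tapply(l$visit_time, l$subject_id, max) > 0)
  })
  expect_gt(mean(n_fu), 85)
  expect_lt(mean(n_fu), 90)

  # missing reserve covariate is an error
  expect_error(simulate_longitudinal(sim$pheno, list(), cfg), "reserve")
})

test_that("CSF harmonization fences log-scale outliers and z-scores the rest", {
  v <- c(10, 11, 12, 13, 1000)
  out <- csf_harmonize(v)
  expect_identical(out$kept, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # hand-checked: type-7 quartiles of log10 values are the 2nd and 4th
  # order statistics; the upper fence lies far below log10(1000)
  lx <- log10(v[1:4])
  expect_equal(out$z[1:4], (lx - mean(lx)) / sd(lx), tolerance = 1e-12)
  expect_true(is.na(out$z[5]))
  expect_lt(abs(mean(out$z[1:4])), 1e-9)
  expect_lt(abs(sd(out$z[1:4]) - 1), 1e-9)

  # identical values: nothing fenced, zero-variance convention gives zeros
  out2 <- csf_harmonize(rep(7, 10))
  expect_true(all(out2$kept))
  expect_true(all(out2$z == 0))

  expect_error(csf_harmonize(c(1, 2)), "at least 3")
  expect_error(csf_harmonize(c(1, -1, 2)), "positive")
})

test_that("Gaussian-mixture cut point respects symmetry and weight imbalance", {
  set.seed(41)
  x <- c(rnorm(1000, -1, 0.3), rnorm(1000, 1, 0.3))
  cut <- gmm_cutpoint(x)
  expect_lt(abs(cut), 0.1)

  # data exactly symmetric about c = 2 puts the cut at 2
  xs <- c(x, 4 - x)
  expect_lt(abs(gmm_cutpoint(xs) - 2), 0.05)

  # unequal weights shift the cut toward the minor component, matching the
  # closed-form equal-posterior solution for the fitted parameters
  set.seed(43)
  xu <- c(rnorm(1600, -1, 0.3), rnorm(400, 1, 0.3))
  cutu <- gmm_cutpoint(xu)
  mix <- attr(cutu, "mixture")
  shift_oracle <- function(m1, m2, s, p1, p2)
    (m1 + m2) / 2 + s^2 * log(p1 / p2) / (m2 - m1)
  expect_gt(cutu, 0)   # toward the minor (positive) component
  expect_lt(abs(cutu - shift_oracle(mix$mean[1], mix$mean[2],
                                    mean(mix$sd), mix$weight[1],
                                    mix$weight[2])), 0.1)

  # bimodal separation at 3.5 component SDs keeps misclassification under 5%
  set.seed(44)
  lab <- rep(c(0, 1), each = 2000)
  xb <- c(rnorm(2000, -1.75), rnorm(2000, 1.75))
  cutb <- gmm_cutpoint(xb)
  expect_lt(mean((xb > cutb) != lab), 0.05)

  expect_error(gmm_cutpoint(rnorm(10)), "at least 20")
})
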