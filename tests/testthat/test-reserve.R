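mrs_fixture <- function() {
  b <- matrix(c(0.5, 0.7,
                0.2, 0.4), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("A", "B")))
  betas <- beta_matrix(b, c("cg1", "cg2"), c("chr1", "chr1"), c(100, 200))
  fits <- data.frame(cpg_id = c("cg1", "cg2"),
                     beta_ptau = c(-0.1, -0.3),
                     estimate = c(0.2, 0.5),
                     stringsAsFactors = FALSE)
  list(betas = betas, fits = fits)
}

test_that("the reserve score is the average DNAm-conditional pTau slope", {
  fx <- mrs_fixture()
  out <- compute_mrs(fx$betas, fx$fits)
  # hand computation: subject A: ((-0.1+0.2*0.5)+(-0.3+0.5*0.2))/2 = -0.10
  #                   subject B: ((-0.1+0.2*0.7)+(-0.3+0.5*0.4))/2 = -0.03
  expect_equal(out$mrs_raw, c(-0.10, -0.03), tolerance = 1e-12)
  # two subjects: z-scores are +/- 1/sqrt(2) * sqrt(2) = +/- 0.7071... with
  # the sample-SD convention sd(c(-.1,-.03)) -> z = (x - mean)/sd
  expect_equal(out$mrs_z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_lt(abs(mean(out$mrs_z)), 1e-9)
  expect_equal(sd(out$mrs_z), 1, tolerance = 1e-9)

  # single CpG with beta = -0.1, gamma = 0.2 at M = 0.5 scores exactly 0
  b1 <- beta_matrix(matrix(c(0.5, 0.9), 1, dimnames = list(NULL, c("A", "B"))),
                    "cg1", "chr1", 100)
  out1 <- compute_mrs(b1, fx$fits[1, ])
  expect_equal(out1$mrs_raw[1], 0, tolerance = 1e-12)

  # all-zero interactions give a constant score: z-score undefined
  fits0 <- fx$fits
  fits0$estimate <- 0
  expect_error(compute_mrs(fx$betas, fits0), "zero variance")

  # a missing fit is an error
  expect_error(compute_mrs(fx$betas, fx$fits[1, ]), "cg2")
})

test_that("the reserve score is affine in each beta value with slope gamma/n", {
  set.seed(3)
  n_cpg <- 5
  b <- matrix(runif(n_cpg * 4, 0.2, 0.8), n_cpg, 4,
              dimnames = list(NULL, paste0("S", 1:4)))
  betas <- beta_matrix(b, paste0("cg", 1:n_cpg), rep("chr1", n_cpg),
                       (1:n_cpg) * 1000)
  fits <- data.frame(cpg_id = paste0("cg", 1:n_cpg),
                     beta_ptau = rnorm(n_cpg, -0.2, 0.05),
                     estimate = rnorm(n_cpg, 0.1, 0.3))
  base <- compute_mrs(betas, fits)
  eps <- 1e-6
  for (j in c(1, 4)) {
    b2 <- b
    b2[j, 2] <- b2[j, 2] + eps
    pert <- compute_mrs(beta_matrix(b2, betas$cpg_id, betas$chrom,
                                    betas$pos), fits)
    deriv <- (pert$mrs_raw[2] - base$mrs_raw[2]) / eps
    expect_equal(deriv, fits$estimate[j] / n_cpg, tolerance = 1e-5)
  }
})

test_that("tertile grouping balances sizes and respects ordering", {
  expect_identical(as.integer(table(tertile_groups(1:9))), rep(3L, 3))
  expect_identical(as.integer(table(tertile_groups(1:10))), c(4L, 3L, 3L))
  x <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  g <- tertile_groups(x)
  expect_true(max(x[g == "low"]) <= min(x[g == "mid"]))
  expect_true(max(x[g == "mid"]) <= min(x[g == "high"]))
  expect_error(tertile_groups(1:2), "at least 3")
})

test_that("with no subject heterogeneity the mixed model collapses to pooled OLS", {
  cfg <- sim_config(n_subjects = 80, n_cpgs = 6, n_signal_cpgs = 2,
                    gamma_range = 0.8, rand_intercept_sd = 0,
                    visit_schedule = "fixed", followup_frac = 1,
                    n_visits = 4, seed = 51)
  sim <- simulate_cohort(cfg)
  long <- simulate_longitudinal(sim$pheno, sim$truth, cfg)
  mrs <- data.frame(subject_id = sim$truth$reserve$subject_id,
                    mrs_z = sim$truth$reserve$reserve,
                    tertile = tertile_groups(sim$truth$reserve$reserve))
  fit <- fit_longitudinal_model(long, sim$pheno, mrs)
  # balanced design: GLS equals OLS on the pooled rows
  dat <- merge(merge(long, sim$pheno[, c("subject_id", "age", "sex", "apoe4",
                                         "education", "ptau_z")],
                     by = "subject_id"), mrs, by = "subject_id")
  sub <- !duplicated(dat$subject_id)
  zs <- function(v) (v - mean(v[sub])) / sd(v[sub])
  dat$baseline_age <- zs(dat$age); dat$baseline_ptau <- zs(dat$ptau_z)
  dat$mrs <- zs(dat$mrs_z); dat$time <- dat$visit_time
  ols <- lm(memory ~ baseline_age + sex + apoe4 + education + mrs + time +
              baseline_ptau + mrs:time + baseline_ptau:time +
              mrs:baseline_ptau, data = dat)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-8)
})

test_that("profiled REML matches lme4 on an unbalanced fixture", {
  skip_if_not_installed("lme4")
  set.seed(42)
  n <- 60
  ph <- data.frame(subject_id = sprintf("S%02d", 1:n), x1 = rnorm(n),
                   x2 = rbinom(n, 1, 0.5))
  rows <- do.call(rbind, lapply(1:n, function(i)
    data.frame(subject_id = ph$subject_id[i], time = 0:sample(1:5, 1))))
  d <- merge(rows, ph)
  b_i <- rnorm(n, 0, 0.7)
  names(b_i) <- ph$subject_id
  d$y <- 1 + 0.5 * d$x1 - 0.3 * d$x2 - 0.1 * d$time + 0.2 * d$x1 * d$time +
    b_i[d$subject_id] + rnorm(nrow(d), 0, 0.4)
  f1 <- fit_random_intercept_lmm(y ~ x1 + x2 + time + x1:time, d)
  f2 <- lme4::lmer(y ~ x1 + x2 + time + x1:time + (1 | subject_id), d,
                   REML = TRUE)
  expect_equal(f1$coefficients$estimate, unname(lme4::fixef(f2)),
               tolerance = 1e-7)
  expect_equal(f1$sigma_b,
               unname(attr(lme4::VarCorr(f2)$subject_id, "stddev")),
               tolerance = 1e-5)
  expect_equal(f1$sigma, sigma(f2), tolerance = 1e-6)
  expect_equal(f1$reml_loglik, as.numeric(logLik(f2)), tolerance = 1e-7)
})

test_that("the REML optimum beats random variance-ratio probes and scaling leaves t intact", {
  cfg <- sim_config(n_subjects = 70, n_cpgs = 6, n_signal_cpgs = 2,
                    gamma_range = 0.8, seed = 61)
  sim <- simulate_cohort(cfg)
  long <- simulate_longitudinal(sim$pheno, sim$truth, cfg)
  mrs <- data.frame(subject_id = sim$truth$reserve$subject_id,
                    mrs_z = sim$truth$reserve$reserve,
                    tertile = tertile_groups(sim$truth$reserve$reserve))
  fit <- fit_longitudinal_model(long, sim$pheno, mrs)
  crit_opt <- fit$profile(fit$theta)
  set.seed(62)
  for (th in exp(runif(20, -8, 4)))
    expect_gte(fit$profile(th), crit_opt - 1e-8)

  # rescaling the reserve covariate rescales its coefficients, not their t
  dat <- merge(merge(long, sim$pheno[, c("subject_id", "age", "sex",
                                         "apoe4", "education", "ptau_z")],
                     by = "subject_id"), mrs, by = "subject_id")
  dat$time <- dat$visit_time
  dat$m1 <- dat$mrs_z
  dat$m2 <- 2 * dat$mrs_z + 1
  fA <- fit_random_intercept_lmm(
    memory ~ age + sex + apoe4 + education + m1 + time + ptau_z +
      m1:time + ptau_z:time + m1:ptau_z, dat)
  fB <- fit_random_intercept_lmm(
    memory ~ age + sex + apoe4 + education + m2 + time + ptau_z +
      m2:time + ptau_z:time + m2:ptau_z, dat)
  tA <- fA$coefficients$t[match(c("m1", "m1:time", "m1:ptau_z"),
                                fA$coefficients$term)]
  tB <- fB$coefficients$t[match(c("m2", "m2:time", "m2:ptau_z"),
                                fB$coefficients$term)]
  expect_equal(tA, tB, tolerance = 1e-7)

  # singular fixed effects are refused
  dat$dup <- dat$age
  expect_error(fit_random_intercept_lmm(memory ~ age + dup + time, dat),
               "singular")
})

test_that("tertile trajectories summarize change from baseline and order by reserve", {
  cfg <- sim_config(n_subjects = 300, n_cpgs = 8, n_signal_cpgs = 3,
                    gamma_range = 0.8, slope_mrs = 0.3, slope_ptau = 0,
                    rand_intercept_sd = 0.3, long_noise_sd = 0.1,
                    visit_schedule = "fixed", n_visits = 5,
                    followup_frac = 1, seed = 71)
  sim <- simulate_cohort(cfg)
  long <- simulate_longitudinal(sim$pheno, sim$truth, cfg)
  mrs <- data.frame(subject_id = sim$truth$reserve$subject_id,
                    mrs_z = sim$truth$reserve$reserve,
                    tertile = tertile_groups(sim$truth$reserve$reserve))
  ts <- trajectory_summary(long, mrs)
  expect_true(all(ts$series$change[ts$series$visit_time == 0] == 0))
  sl <- ts$slopes$slope[match(c("low", "mid", "high"), ts$slopes$tertile)]
  expect_true(sl[1] < sl[2] && sl[2] < sl[3])

  # flat trajectories give zero slopes in every group
  cfg0 <- cfg
  cfg0$slope_base <- cfg0$slope_ptau <- cfg0$slope_mrs <- 0
  cfg0$rand_intercept_sd <- cfg0$long_noise_sd <- 0
  long0 <- simulate_longitudinal(sim$pheno, sim$truth, cfg0)
  ts0 <- trajectory_summary(long0, mrs)
  expect_true(all(abs(ts0$slopes$slope) < 1e-10))

  # subjects without a baseline row are dropped with a warning
  long_nb <- long[!(long$subject_id == long$subject_id[1] &
                      long$visit_time == 0), ]
  expect_warning(trajectory_summary(long_nb, mrs), "baseline")

  # the tertile re-fit flags faster decline in the low-reserve group
  fitT <- fit_longitudinal_model(long, sim$pheno, mrs, use_tertiles = TRUE)
  lt <- fitT$coefficients
  expect_lt(lt$estimate[lt$term == "mrs_low:time"], 0)
  expect_lt(lt$p[lt$term == "mrs_low:time"], 0.05)
})
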