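# Independent oracles shared across test files. These deliberately use
# different computational routes than the package (explicit normal
# equations, brute-force step-up, closed forms, EM on the mixed-model
# equations) so agreement is evidence, not tautology.

# explicit (X'X)^-1 X'y least squares with standard errors
ols_oracle <- function(X, y) {
  XtXi <- solve(t(X) %*% X)
  coef <- XtXi %*% t(X) %*% y
  res <- y - X %*% coef
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coef = unname(as.numeric(coef)), se = unname(sqrt(diag(s2 * XtXi))),
       sigma = sqrt(s2), vcov = unname(s2 * XtXi),
       resid = unname(as.numeric(res)))
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(n), function(i) min(pmin(ps[i:n] * n / (i:n), 1)),
               numeric(1))
  q <- numeric(n)
  q[o] <- qs
  q
}

# closed-form bivariate correlation-adjusted Stouffer combination
stouffer2_oracle <- function(p1, p2, rho) {
  z1 <- qnorm(p1, lower.tail = FALSE)
  z2 <- qnorm(p2, lower.tail = FALSE)
  pnorm((z1 + z2) / sqrt(2 + 2 * rho), lower.tail = FALSE)
}

# textbook Spearman for distinct values: 1 - 6*sum(d^2)/(n(n^2-1))
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# EM-REML for the random-intercept model via Henderson's mixed-model
# equations (Searle-style variance-component updates)
em_reml_oracle <- function(y, X, grp, max_iter = 2e5, tol = 1e-13) {
  Z <- stats::model.matrix(~ 0 + factor(grp))
  p <- ncol(X); m <- ncol(Z); N <- length(y)
  XtX <- crossprod(X); XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  Xty <- crossprod(X, y); Zty <- crossprod(Z, y)
  sb2 <- stats::var(y) / 2
  s2 <- stats::var(y) / 2
  for (it in seq_len(max_iter)) {
    k <- s2 / sb2
    C <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ + diag(k, m)))
    Ci <- solve(C)
    sol <- Ci %*% c(Xty, Zty)
    beta <- sol[1:p]; u <- sol[-(1:p)]
    sb2_new <- (sum(u^2) + s2 * sum(diag(Ci[-(1:p), -(1:p)]))) / m
    s2_new <- sum(y * (y - X %*% beta - Z %*% u)) / (N - p)
    done <- abs(sb2_new - sb2) + abs(s2_new - s2) < tol
    sb2 <- sb2_new; s2 <- s2_new
    if (done) break
  }
  k <- s2 / sb2
  C <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ + diag(k, m)))
  sol <- solve(C, c(Xty, Zty))
  list(beta = as.numeric(sol[1:p]), sigma_b = sqrt(sb2), sigma = sqrt(s2),
       iterations = it)
}

# frozen spiked-region fixture: an 8-probe mid-methylated region strong
# enough (median per-probe p ~ 1e-5 at n = 92) that the region should be
# recoverable at Sidak < 0.05 in the large majority of seeds; the within-
# region correlation keeps probe signs coherent for the direction filter
dmr_spike_config <- function(seed, n_cpgs = 400, gamma_effect = 1.5) {
  sim_config(n_subjects = 92, n_cpgs = n_cpgs, noise_sd = 0.4, ar_rho = 0.7,
             dmr_specs = list(list(chrom = "chr7", start_pos = 5000101L,
                                   n_probes = 8L, probe_spacing = 100L,
                                   gamma_effect = gamma_effect, sign = 1,
                                   mu = 0)),
             seed = seed)
}

spike_rows <- function(ewas) {
  ewas$chrom == "chr7" & ewas$pos >= 5000101 & ewas$pos <= 5000801
}

# a small fake scan result for region/filter tests that do not need a fit
fake_ewas <- function(chrom, pos, p, estimate, iqr = 0.1) {
  out <- data.frame(cpg_id = sprintf("cg%05d", seq_along(pos)),
                    chrom = chrom, pos = pos, estimate = estimate,
                    std_err = 1, t = estimate, p_value = p,
                    iqr = iqr, fit_ok = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("ewas_result", "data.frame")
  out
}
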