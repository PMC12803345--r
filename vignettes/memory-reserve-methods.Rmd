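---
title: "Methods: moderation analysis of DNA methylation and memory reserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderation analysis of DNA methylation and memory reserve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memreserve)
```

## The scientific question

Cognitive reserve describes why two people with the same burden of
Alzheimer's pathology can differ widely in cognitive performance. The most
direct statistical operationalization is *moderation*: a reserve factor is
one that attenuates the association between a pathology measure and a
cognitive outcome. `memreserve` implements this moderation analysis for
blood DNA methylation in prodromal disease: the pathology index is CSF
pTau181 (z-scored), the outcome is a harmonized memory composite, and the
candidate moderators are methylation beta values at individual CpGs.

## Model 1: the per-CpG moderation model

Memory is first residualized on nuisance covariates — age, sex, APOE4
allele count, and the major immune cell-type proportions
(`residualize_memory()`). Cell proportions are compositional (they sum to
one), so the granulocyte column is dropped from the design; which column is
dropped is configurable and does not change the fitted residuals. Education
is deliberately *not* in this covariate set; it enters only the
longitudinal model below.

At each CpG the covariate-adjusted memory score $y$ is modeled as

$$y = \alpha + \beta\,p + \tau M + \gamma\,M p + \varepsilon,$$

where $p$ is z-scored pTau181 and $M$ the beta value
(`fit_interaction_model()`, vectorized by `run_ewas()`). The moderation
parameter is $\gamma$: with $\beta < 0$ (higher pTau, worse memory), a
positive $\gamma$ means higher methylation weakens the harmful association.
The pTau slope at methylation level $m$ is $\beta + \gamma m$
(`slope_at_dnam()`), typically displayed at the 25th and 75th percentiles
of $M$. Inference on $\gamma$ uses the OLS t statistic with $n-4$ degrees
of freedom; degenerate probes (constant $M$) are flagged and carried
through the scan rather than aborting it.

Two filters mirror standard practice: probes with beta-value interquartile
range at or below 0.02 are treated as uninformative (`iqr_filter()`;
quantiles use the linear-interpolation, type-7 convention throughout the
package, which matters exactly at such thresholds), and samples whose PC1
or PC2 score lies more than 3 SDs from the mean are removed
(`pca_outlier_filter()`). The "outside 3 SDs" rule is implemented
two-sided; a one-sided reading exists but a sample displaced in either
direction along a dominant variance axis is equally suspect.

## Empirical-null correction

Genome-wide interaction statistics are mildly miscalibrated by unmeasured
confounding and by the two-stage residualize-then-scan design. The
inflation factor $\lambda$ (`genomic_lambda()`) summarizes this as
median$(z^2)/0.4549$. `fit_bacon()` models the z statistics as a
three-component Gaussian mixture whose dominant central component is the
empirical null $N(\mu_0, \sigma_0^2)$; $\mu_0$ is the bias and $\sigma_0$
the inflation. `bacon_correct()` rescales $z \mapsto (z-\mu_0)/\sigma_0$
(with matching effect/SE updates, preserving effect/SE $= z$), and
`bh_fdr()` / `call_suggestive()` apply FDR and the suggestive threshold
$p < 10^{-5}$ (strict), reported both before and after the IQR filter.

Numerical choices, made once and pinned by tests:

* Estimation is by EM with seeded restarts rather than a posterior sampler:
  the estimand (the central component's mean and SD) is the same and the
  procedure is deterministic given a seed.
* The likelihood is evaluated on a 2048-bin histogram of $z$. At genome
  scale the bin width is of order $10^{-3}$ SD, so the approximation error
  is far below the statistical error, and each EM pass costs O(bins).
* The flanking (signal) component means are constrained to lie at least
  $1.5\,\sigma_0$ from $\mu_0$. With a looser constraint the flanking
  components absorb the null's own tails, biasing $\mu_0$ and $\sigma_0$;
  at $1.5\,\sigma_0$ a generating null of $N(-0.058, 1.06^2)$ is recovered
  to the third decimal.
* t statistics are treated as z (the residual df, $n-4 \approx 88$, makes
  this a sub-percent approximation).

## Differentially methylated regions

Region detection follows the comb-p logic on the interaction p-values:

1. `estimate_acf()` bins same-chromosome probe pairs by distance (default
   50 bp bins up to 750 bp) and estimates the correlation of the one-sided
   z transforms per bin. Negative estimates are clipped to zero before use
   so combined variances are never deflated.
2. `slk_smooth()` combines each probe with its neighbours within a 750 bp
   window by the correlation-adjusted Stouffer statistic
   $z_c = \sum z_i / \sqrt{\sum_{ij}\rho(d_{ij})}$.
3. `find_regions()` seeds a region at any smoothed $p < 0.05$ and extends
   it while consecutive qualifying probes are at most 750 bp apart
   (inclusive gap comparison, pinned by a boundary test). Intervals are
   0-based half-open.
4. `region_pvalue()` re-scores each candidate from the *original*
   p-values under the binned correlation; `sidak_adjust()` corrects for
   multiplicity with exponent total-covered-bases / region-length, where
   the covered total sums per-probe spacing capped at twice the window
   (the cap also stands in for each chromosome's last probe). The exact
   denominator used in the original software's runs is not recoverable
   from its outputs, so this definition is explicit and configurable.
5. `direction_filter()` keeps only regions whose interaction estimates
   share one sign (a zero estimate counts as inconsistent) and records the
   per-probe direction string. Reported regions need at least 3 probes.

## The Methylation Reserve Score and the longitudinal model

`compute_mrs()` averages the DNAm-conditional pTau slope
$\beta_j + \gamma_j M_{ij}$ over the selected CpGs (suggestive hits plus
DMR members): lower scores mean a more harmful pTau effect, higher scores
mean attenuation — more reserve. The raw per-CpG OLS estimates feed the
score by default because the score's definition references the moderation
model directly; a flag switches to empirical-null-corrected estimates.
Scores are z-scored with the sample SD ($n-1$) and split into tertiles
(`tertile_groups()`; sizes differ by at most one, ties broken by stable
input order).

Model 2 relates baseline reserve to memory trajectories
(`fit_longitudinal_model()`): memory on baseline age, sex, APOE4,
education, MRS, baseline pTau, time, and the MRS×time, pTau×time and
MRS×pTau interactions, with a subject random intercept. Baseline age,
pTau and MRS are z-scored over the analysis sample. The fit
(`fit_random_intercept_lmm()`) is restricted maximum likelihood, profiled
to the single variance ratio $\theta = \sigma_b^2/\sigma^2$: for fixed
$\theta$ the GLS solve is OLS on partially subject-demeaned data, so a
one-dimensional search on $\log\theta$ (with the $\theta = 0$ boundary
checked explicitly) locates the optimum. Fixed-effect tests use Wald t
with $n_{\text{obs}} - n_{\text{fixed}}$ df — a large-sample choice, not a
Satterthwaite adjustment, so p-values for between-subject terms are
slightly anti-conservative in small samples; the package's recovery tests
are therefore phrased in terms of estimates and CI coverage rather than
p-value equality with any particular reference tool. The tertile re-fit
replaces the continuous score with low/mid indicators (high as reference).

## Downstream: pathways and cross-tissue concordance

`gene_pvalue_rra()` aggregates the CpG p-values mapped to each gene by the
robust-rank statistic $\rho = \min_j \Pr\{\mathrm{Beta}(j,k-j+1) \le
p_{(j)}\}$ with a Bonferroni factor $k$ for the CpG count — conservative
under the null by construction. `preranked_gsea()` ranks genes by
$-\log_{10}$ gene p (ties broken by name for determinism) and runs the
weighted Kolmogorov–Smirnov enrichment with gene-label permutations;
normalized scores divide by the mean same-sign null magnitude. Sets are
restricted to 5–200 present genes and a set is only called significant at
25% FDR if its leading edge holds at least three genes, so one or two
extreme genes cannot carry a pathway. `brain_blood_correlation()` computes
Spearman correlations between matched tissue profiles, either raw or on
residuals after regressing each tissue on its own covariates.

## The synthetic cohort generator

`simulate_cohort()` emulates the study sample: 92 subjects by default, age
74.67 (SD 7.51), 44.6% female, 52% APOE4 carriers, education 16.21 (SD
2.78), 43% ever-smokers, Dirichlet cell proportions around typical
whole-blood fractions, and lognormal pTau181 moment-matched to mean 46.46
/ SD 27.32 pg/mL, then z-scored. Betas are logit-normal: normal marginals
on the logit scale mapped through the inverse logit, which keeps values
strictly in (0,1); probes inside spiked regions share a stationary AR(1)
latent process with configurable correlation, and a configurable fraction
of background probes is generated near-constant to exercise the IQR
filter. Background probe positions use lognormal inter-probe gaps (median
1.5 kb) so that sub-750 bp probe pairs exist genome-wide, as on a real
array — the autocorrelation estimator needs such pairs under the null.

Memory is generated from the moderation model itself. Spiked interaction
and main effects enter *centered at each CpG's cohort-mean methylation*:
this makes `beta_ptau` the pTau slope at average methylation (the
interpretable quantity) rather than at the impossible $M=0$, and it is an
exact reparameterization of the uncentered form. It also keeps the
generator honest for power studies: uncentered spikes of region scale add
an enormous coherent pTau slope whose interplay with the two-stage
residualization floods the interaction test with artifact noise — a regime
real per-CpG effects (of order 0.06 memory units per SD per unit beta) do
not approach.

`simulate_longitudinal()` adds visits: every subject has a baseline row at
time 0, a configurable fraction (default 95%, matching the 88-of-92
follow-up pattern) receives follow-ups — annually for up to 6 years by
default, a schedule the source data do not pin down and which is therefore
configurable, not claimed. Trajectories follow a random-intercept model
whose slope carries baseline-pTau and reserve components; defaults for the
slope and baseline terms are the reported longitudinal estimates
(−0.050/yr decline, +0.034 reserve-by-time, +0.217 reserve-by-pTau,
−0.026 pTau-by-time). The truth table records per-CpG effects and each
subject's true reserve (the z-scored generative analogue of the MRS), so
recovery tests have ground truth.

What the generator does *not* emulate: probe chemistry, batch structure,
cell-composition shifts correlated with methylation, missingness, or
genuine biological annotation — so passing tests demonstrate statistical
correctness of the pipeline, not robustness to array artifacts.

## Problem sizes and reproducibility

The test-suite simulations use cohorts of 92–500 subjects and 4–2000 CpGs:
type-I calibration uses 20 cohorts of 2000 null CpGs; region-detection
power uses 50 cohorts with an 8-probe spiked region calibrated to a median
per-probe p near $10^{-4}$ (mid-methylated region, `mu = 0`, AR 0.5,
`gamma_effect = 1.2`, noise SD 0.4); longitudinal coverage uses 100
cohorts of 500 subjects with 5 fixed visits. All randomness flows from
integer seeds, and `scripts/acceptance.R` recomputes the headline
quantities from scratch for any seed.

## Known limitations

* The empirical-null EM is a point-estimate procedure; it does not
  propagate uncertainty in $(\mu_0, \sigma_0)$ into corrected p-values.
* The mixed model supports random intercepts only — no random slopes —
  and its df convention is asymptotic (see above).
* The Sidak denominator is a modeling choice (documented above); region
  p-values depend on the estimated autocorrelation, which in sparse
  regions is informed by few pairs.
* Cross-tissue correlation assumes matched sample order and complete
  covariates; it performs no batch harmonization of its own.
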