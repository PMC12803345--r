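# memreserve

Moderation analysis of blood DNA methylation and memory reserve in
prodromal Alzheimer's disease.

## What it does

Cognitive reserve is the observation that the same burden of Alzheimer's
pathology impairs some people far less than others. The most direct
statistical reading of reserve is **moderation**: a marker confers reserve
if it attenuates the association between pathology and cognition.
`memreserve` implements this analysis end to end for blood DNA methylation
(DNAm), CSF pTau181 as the pathology index, and a harmonized memory
composite as the outcome:

1. **Covariate adjustment** — memory is residualized on age, sex, APOE4
   count and immune cell-type proportions (`residualize_memory()`).
2. **Per-CpG moderation scan** — at every CpG, OLS of adjusted memory on
   pTau, methylation, and their product:
   `y = α + β·p + τ·M + γ·M·p + ε`; the interaction `γ` is the moderation
   effect and `β + γ·m` the pTau slope at methylation level `m`
   (`run_ewas()`, `slope_at_dnam()`).
3. **Empirical-null correction** — a three-component Gaussian mixture fit
   to the genome-wide z statistics estimates the bias and inflation of the
   null; statistics are rescaled and FDR / suggestive (p < 1e-5) calls made
   before and after a low-variability (IQR ≤ 0.02) filter (`fit_bacon()`,
   `bacon_adjust_ewas()`, `call_suggestive()`).
4. **Region detection** — correlation-adjusted Stouffer-Liptak smoothing,
   seed-and-extend regions (seed 0.05, extension 750 bp), Sidak
   multiplicity control, and a consistent-direction filter
   (`detect_dmrs()`).
5. **Pathways and cross-tissue checks** — gene-level p-values by robust
   rank aggregation with Bonferroni for CpG count, pre-ranked GSEA with
   gene-label permutations, and Spearman blood-brain correlations
   (`gene_pvalue_rra()`, `preranked_gsea()`, `brain_blood_correlation()`).
6. **Methylation Reserve Score** — the average DNAm-conditional pTau slope
   over the selected CpGs, z-scored; evaluated against longitudinal memory
   decline with a random-intercept REML mixed model including MRS×time,
   pTau×time and MRS×pTau terms (`compute_mrs()`,
   `fit_longitudinal_model()`).

A synthetic-cohort generator (`simulate_cohort()`,
`simulate_longitudinal()`) reproduces the study conditions — 92
amyloid-positive MCI-like subjects, pTau181 mean 46.46 / SD 27.32 pg/mL,
logit-normal betas with correlated spiked regions — with a ground-truth
table, so every stage can be exercised against known effects.

## Worked example

Simulate a cohort with two spiked CpGs and one spiked 8-probe region, run
the full pipeline, and relate the resulting reserve score to simulated
memory trajectories:

```r
library(memreserve)

cfg <- sim_config(
  n_subjects = 92, n_cpgs = 2000, n_signal_cpgs = 2, gamma_range = 3,
  dmr_specs = list(list(chrom = "chr19", start_pos = 50983852, n_probes = 8,
                        probe_spacing = 100, gamma_effect = 1.8, sign = -1,
                        mu = 0)),
  noise_sd = 0.4, ar_rho = 0.5, seed = 2024)
sim   <- simulate_cohort(cfg)
pheno <- residualize_memory(sim$pheno)
ewas  <- bacon_adjust_ewas(run_ewas(sim$betas, pheno), seed = 7)
attr(ewas, "bacon_params")
#> bacon_params: bias mu0 = -0.1576, inflation sigma0 = 1.436 (null weight 0.958)
#>   lambda GC pre = 2.328, post = 1.108
```

The strong planted effects inflate the raw statistics (lambda 2.33); the
empirical-null correction brings them back near 1. The suggestive CpGs and
the spiked region are recovered with the right (negative) direction:

```r
dmrs <- detect_dmrs(ewas)
dmrs
#>   chrom    start      end n_probes     p_region    sidak_p direction
#> 1 chr19 50983852 50984553        8 6.777025e-06 0.02094936  --------
```

Score each subject by the average DNAm-conditional pTau slope over the
suggestive and region CpGs, then fit the longitudinal model:

```r
hits <- call_suggestive(ewas)
sel  <- unique(c(hits$post$cpg_id,
                 sim$betas$cpg_id[sim$betas$chrom == "chr19" &
                                  sim$betas$pos >= dmrs$start[1] &
                                  sim$betas$pos <  dmrs$end[1]]))
mrs  <- compute_mrs(subset_cpgs(sim$betas, sel), ewas)
long <- simulate_longitudinal(sim$pheno, sim$truth, cfg)
fit_longitudinal_model(long, sim$pheno, mrs)
#> Random-intercept LMM (REML): 344 obs, 92 subjects
#>   sigma_b = 0.5071, sigma = 0.1528, REML logLik = -32.5510
#>                term estimate       se       t         p
#>                 ...
#>                time -0.05324 0.006515 -8.1710 6.427e-15
#>            mrs:time  0.02846 0.006605  4.3080 2.166e-05
#>  time:baseline_ptau -0.02997 0.006330 -4.7350 3.252e-06
#>   mrs:baseline_ptau  0.11220 0.055160  2.0340 4.276e-02
```

Memory declines over time (`time` < 0), higher pTau accelerates decline
(`time:baseline_ptau` < 0), and a higher reserve score both slows decline
(`mrs:time` > 0) and attenuates the baseline pTau-memory association
(`mrs:baseline_ptau` > 0) — the moderation signature the pipeline is built
to detect. The generating values here were −0.050, −0.026 and +0.034 per
year and +0.217 for the baseline interaction; each estimate lands within
its confidence interval.

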