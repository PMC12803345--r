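Package: memreserve
Title: Epigenome-Wide Moderation Analysis of Memory Reserve
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for identifying blood DNA methylation loci that moderate
    the association between CSF tau pathology (pTau181) and memory in
    prodromal Alzheimer's disease. Implements per-CpG interaction (moderation)
    models on covariate-adjusted memory scores, empirical-null correction of
    genome-wide test statistics via a three-component Gaussian mixture,
    autocorrelation-adjusted Stouffer-Liptak detection of differentially
    methylated regions with Sidak multiplicity control, gene-level p-value
    aggregation with pre-ranked gene set enrichment analysis, blood-brain
    cross-tissue correlation, and a Methylation Reserve Score evaluated
    against longitudinal memory decline with a random-intercept mixed model.
    A synthetic-cohort generator with known moderation structure supports
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    lme4,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
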