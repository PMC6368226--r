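# emtsig

Derivation, cross-cohort translation and survival evaluation of a
TGF-beta-induced EMT gene-expression signature.

## What this is for

Lung adenocarcinoma cell lines differ in whether TGF-beta-1 drives them
through an epithelial-to-mesenchymal transition (EMT). Contrasting
responder against non-responder lines isolates the transcriptional program
specific to TGF-beta-*induced* EMT, and a signature built from that
contrast can be scored in tumor cohorts to stratify patients by metastatic
risk. `emtsig` implements that full analysis path for transcriptomics
practitioners:

1. **Screen** — log2 ratios versus each line's untreated controls, seven
   fixed two-group comparisons, and a sign-agreement fold-change call
   (|Δ| ≥ 0.585 log2, i.e. 1.5-fold): probesets are categorized
   EMT-related, no-EMT-related or TGF-beta-related by triple consistency
   across comparisons, with opposite-phenotype conflicts removed.
2. **Prune** — keep EMT-related probesets with complete group separation
   in ≥ 1 comparison, a 2-fold cutoff on the worst of the three EMT
   comparisons, and Welch-t and Mann-Whitney p < 0.002 there; merge a
   curated include-list.
3. **Translate** — per tumor cohort, PCA on the autoscaled signature
   genes; orient PC1 by majority loading-sign agreement and drop probesets
   whose loading sign contradicts their cell-line direction in most
   cohorts.
4. **Score & stratify** — a sample's signature score is its oriented PC1
   coordinate; split cohorts at the median score or by 2-cluster k-means.
5. **Evaluate** — Kaplan-Meier curves, log-rank tests and fixed-horizon
   survival differences for overall and metastasis-free survival (MFS:
   metastasis and death both count, baseline-metastatic patients
   excluded); Welch t-tests of score versus group labels; per-gene Fisher
   exact mutation enrichment between high/low clusters.

Every input the pipeline consumes can be generated synthetically with
planted ground truth (`simulate_*` functions), so each stage is testable
offline; the shipped reference signature carries the published 77 gene
symbols with synthetic probeset identifiers.

## Worked example

```r
library(emtsig)

sim <- simulate_cellline_experiment(seed = 7)        # 13 lines, 300 probesets
fit <- derive_signature(sim$expression, sim$annotation)
fit
#> EMT signature derivation
#>   screen groups: 8 EMT / 16 no-EMT / 24 untreated samples (4 excluded)
#>   funnel: 300 probesets -> 60 EMT-related (0 conflicts) -> 59 strongest -> 59 with curated
#> EMT signature 'cell-line signature': 59 probesets, 59 genes (30 up, 29 down)

cohort <- simulate_tumor_cohort(sig = fit$signature, seed = 8)
scored <- predict(fit, cohort$expression, split = "median")
scored
#> scored cohort: 300 samples (PC1 79.9% variance, 59 probesets, orientation -1)
#>   groups: 150 high / 150 low (median split)

rec <- build_endpoint(cohort$annotation, "MFS", horizon_months = 60)
grp <- scored$group[match(rec$sample_id, scored$sample_id)]
hi  <- rec[grp == "high", ]; lo <- rec[grp == "low", ]
logrank_test(hi, lo)
#> log-rank test: chi-square = 36.81 (1 df), p = 1.299e-09
delta_surv(km_estimate(hi), km_estimate(lo), 36)
#> [1] -29.1
```

Reading the output: the derivation funnel recovered 59 of the 60 planted
EMT probesets with no false positives; in a fresh simulated cohort whose
latent EMT activity drives both expression and hazards, the high-score
half has markedly worse metastasis-free survival — 29 percentage points
lower at 36 months — exactly the direction the signature is meant to
detect (negative Δ = worse survival in the high group).

`run_pipeline(pipeline_config(seed = 1), out_dir = "out")` chains all
stages (simulate → derive → translate → score → survive → associate) and
writes the signature, scores, a JSON run report with the stage funnel, and
the resolved YAML config.

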