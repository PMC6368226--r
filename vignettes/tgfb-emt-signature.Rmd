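---
title: "Deriving, translating and evaluating a TGF-beta EMT expression signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving, translating and evaluating a TGF-beta EMT expression signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtsig)
```

## The problem

Transforming growth factor beta (TGF-beta) can push epithelial tumor cells
into an epithelial-to-mesenchymal transition (EMT), a phenotypic shift that
is widely implicated in the first steps of metastasis. Lung adenocarcinoma
cell lines differ in whether they undergo EMT when exposed to TGF-beta-1,
which makes a panel of responder and non-responder lines a natural contrast
for isolating the transcriptional program specific to TGF-beta-*induced*
EMT, as opposed to the generic TGF-beta response shared by all treated
lines. The package implements that derivation, the transfer of the
resulting signature into tumor cohorts, PC1-based patient scoring, and the
downstream survival and association analyses, together with seeded
synthetic-data generators so every stage can be exercised and verified
offline.

## Derivation model

The input is a probesets-by-samples matrix of log2 intensities from a
multi-cell-line treatment time course. Because basal expression differs
strongly between lines, all analysis runs on **log2 ratios**: each sample
minus the mean of its own line's untreated controls
(`compute_log_ratios()`). Samples are grouped as *Untreated* (all untreated
samples of non-excluded lines), *EMT* (treated samples of responder lines),
*no-EMT* (treated samples of non-responder lines) and *TGF-beta* = EMT +
no-EMT; constitutively mesenchymal lines are excluded from every group but
still ship untreated controls for ratioing. Treated samples of all time
points enter their group together.

Seven fixed two-group comparisons are screened (`enumerate_comparisons()`):
EMT vs no-EMT, vs other, vs Untreated; the same three with no-EMT as the
experimental group; and TGF-beta vs Untreated. A probeset is called in a
comparison when the experimental-group mean and the group-mean difference
agree in sign and |difference| >= 0.585 log2 (1.5-fold, inclusive).
Categorization then demands *triple consistency*: EMT-related probesets
carry one non-zero sign across all three EMT comparisons with any non-zero
no-EMT call opposing it; no-EMT-related is symmetric; TGF-beta-related
requires agreement of the three versus-Untreated calls. Probesets
satisfying both the EMT and no-EMT rules are conflicts and are dropped
outright. The triple-consistency requirement is what suppresses false
positives — the null-calibration test (pure noise at the design's group
sizes) measures an EMT-related call fraction far below 1%.

Pruning to the strongest set (`strongest_filter()`) adds three conditions
on the EMT comparisons: complete separation (strictly no overlap between
the two groups' values) in at least one comparison; a 2-fold (1.0 log2)
cutoff on the *worst* (smallest |difference|) of the three; and, on that
same worst comparison, two-sided Welch t and Mann-Whitney U p-values both
below 0.002. The sentence defining the rule attaches both clauses to the
worst comparison, so that is the default; requiring the dual test on all
three comparisons is available via `filter_config(p_on_all_three = TRUE)`.
No multiple-testing correction is applied at either stage, matching the
original screening design; the Mann-Whitney test is exact when both groups
have at most 10 samples and a continuity-corrected normal approximation
otherwise. The curated include-list (seven probesets over six genes of
general EMT interest) is merged afterwards with provenance flags.

## Translation into tumors

Cell-line biology does not transfer wholesale to tumors, so the signature
is filtered against tumor cohorts (`translation_filter()`). Per cohort the
expression is subset to signature probesets, autoscaled (rows to mean 0,
sd 1) and decomposed by PCA; PC1 is oriented so the majority of loading
signs match the cell-line directions, and a probeset *agrees* when its
oriented loading sign equals its direction. Probesets agreeing in at most
half of the evaluable cohorts are removed. Design choices made where the
procedure was genuinely open: only PC1 votes (it carries the signature
axis; no numeric rule involving PC2 was available to adopt), zero loadings
count as disagreement, and probesets evaluable in no cohort are retained
because there is no evidence against them. The vote makes removal
invariant to a global sign flip of any cohort and to cohort ordering.

## Scoring and stratification

`score_cohort()` projects a cohort onto PC1 of its autoscaled
signature-gene expression. The component sign is fixed from the loadings
alone — flip scores and loadings together when the loading-direction
correlation is negative — so "high score = more mesenchymal" is
deterministic and scoring never peeks at outcomes. One consequence worth
stating plainly: because the score is linear in the data and the
orientation criterion is negation-invariant, negating a cohort's values
negates its scores exactly (the loading-sign decisions, and hence
translation removals, are unchanged); the tests pin this behaviour.
Stratification is either a median split (ties and the median itself go
low) or a two-cluster k-means on the autoscaled signature genes
(`stats::kmeans`, best of 10 random restarts under a fixed seed — a
random-restart initialization rather than k-means++ seeding, which the
base implementation does not offer), with the higher-mean-score cluster
labelled high. Autoscaled expression is used for k-means since the score
itself is defined on that scale.

## Survival and association analyses

`build_endpoint()` constructs overall survival (time to death or last
contact) and metastasis-free survival (metastasis and death both count as
events; patients metastatic at surgery are excluded). Fixed-horizon
analyses administratively censor follow-up beyond 36 or 60 months — a
truncation reading of "3-year/5-year", labelled as such in outputs.
Kaplan-Meier curves and the two-group log-rank test are delegated to the
`survival` package behind the package's own interfaces, with events
preceding censorings at tied times; the test suite checks both against
hand-computed product-limit and O/E/V-table oracles. `delta_surv()`
reports S_high(t) − S_low(t) in percentage points, so worse survival in
the high-score group is negative. Score-versus-group comparisons (colon
metastasis at surgery, per-gene WT-vs-mutant) use a two-sided Welch t-test
(a rank-sum alternative sits behind a flag; the original test is unnamed
for the mutation panels). Cluster-versus-mutation enrichment uses the
two-sided Fisher exact test (small-p-values definition) per gene, with
sample odds ratios (infinity allowed) and Benjamini-Hochberg q-values
reported alongside the nominal p-values that drive the ranking.

## What the synthetic data emulate

The generators are pure functions of `(config, seed)` and their defaults
are the study conditions of the test suite:

* **Cell-line experiment** (`simulate_cellline_experiment()`): 4 responder,
  8 non-responder and 1 constitutively mesenchymal line; two untreated
  controls and two treated time points (24 h, 72 h) per line; 30 EMT-up,
  30 EMT-down, 15 no-EMT, 15 shared-TGF-beta and 210 null probesets;
  treatment effect 1.5 log2; residual noise sd 0.3; per-line baseline sd
  1.0. The line counts mirror the real contrast (4 responders vs 8
  non-responders plus one excluded mesenchymal line); effect and noise
  were fixed once at values typical of a strong microarray response so the
  recovery properties hold with margin at this scale.
* **Tumor cohorts** (`simulate_tumor_cohort()`): n = 300 patients with a
  standard-normal latent EMT activity z; signature genes express
  `direction * beta * z` (beta = 1) over noise sd 0.5 plus 50 null genes;
  metastasis and death are two exponential clocks sharing z in their
  log-hazards (baselines 0.02 and 0.01 per month, coefficient gamma =
  0.7), with uniform censoring on [0, 120] months. The two-clock
  construction reproduces the composite MFS endpoint without asserting
  biology the derivation does not need.
* **Colon-style cohort** (`simulate_colon_cohort()`): 96 patients (the
  published cohort's size), 25% metastatic at surgery, whose latent
  activity is shifted by +1 sd.
* **Mutation cohorts** (`simulate_mutation_cohort()`): carrier
  probabilities that depend on the sign of z — 0.40/0.05 for the planted
  low-cluster genes (KEAP1, HGF), mirrored for the high-cluster gene
  (ZNF831), constant for null genes.

What the generators deliberately do **not** reproduce: realistic
microarray intensity distributions, probe-level artifacts, batch
structure (beyond an optional additive batch-mean stand-in,
`remove_batch_means()`, off by default), inter-gene correlation beyond the
single latent axis, or non-proportional hazards. Passing tests therefore
demonstrate that the *procedures* are implemented correctly and behave as
designed under their stated assumptions — not that the signature's
published prognostic performance is reproduced, which would require the
original cohorts and their preprocessing chain. For the same reason the
packaged reference signature ships the published 77 gene symbols with
*synthetic* probeset identifiers: the original array IDs, the per-gene
probeset multiplicities and the per-gene directions are not printed in
full, so the fixture documents those assumptions (13 marked symbols taken
as down-regulated; second probesets assigned to the first 28 symbols
alphabetically; LTBP1 carrying the doubled curated probeset).

## Numerical choices and degenerate inputs

* Normalization against the median sample is implemented as additive
  median-reference scaling on the log2 scale (the reference is the sample
  whose median is closest to the median of per-sample medians); it is
  idempotent and exercised only by tests, since synthetic data are
  generated on a common scale. Rank-invariant normalization internals are
  out of scope.
* PCA is always on autoscaled (correlation-scale) data, via SVD; loading
  columns are unit-norm and deterministically sign-fixed (largest-magnitude
  entry positive) before any downstream orientation.
* Zero-variance probesets are dropped with a warning rather than erroring,
  because subsetting small cohorts to signature genes can produce them;
  an all-constant matrix is an error.
* Complete separation uses strict inequalities: boundary ties count as
  overlap.
* Groups of size one get p-values of 1 (with a warning); zero-variance
  t-test inputs fall back to p = 1 for equal means and p = 0 otherwise.
* All-equal scores cannot be median-split and raise an error; k-means on
  identical points errors rather than fabricating clusters.
* Pipeline artifacts are written atomically (temp file, then rename), and
  every stage failure is labelled with the stage name.

## Problem sizes used by the checks

The automated checks run the derivation on 300-probeset, 52-sample
simulated experiments (20 replicates), null calibration at the same scale,
log-rank calibration and power on 100 seeded cohorts of 150–300 patients,
and translation tests on triplets of 150-patient cohorts — sizes chosen so
the whole battery completes in well under a minute on one core while the
binomial margins on the rate-based assertions stay comfortable.

## Known limitations

* The exact historical probeset identities (1,201 → 135 → 105 on real
  arrays) depend on the original normalization chain and array annotation
  and are not reproducible from printed information; the package
  reproduces the *rules*, and its fixtures the printed gene lists.
* The translation vote is a documented formalization (strict majority on
  PC1 sign agreement) of a procedure originally described visually.
* Only two-group survival contrasts are provided — no Cox models,
  competing risks or confidence bands.
* The NanoString 60-gene reduction is supported as include-list mechanics
  (`apply_include_list()`); codeset-availability logic is out of scope.
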