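---
title: "Methods behind the Random Forests Relapse Score pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the Random Forests Relapse Score pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfrs)
```

## The problem and the model

Node-negative, ER-positive, HER2-negative breast cancer has a favorable
prognosis under hormonal therapy alone, yet a minority of patients relapse
within ten years. The clinical question is which patients can safely be
spared adjuvant chemotherapy. This package implements a transcription-based
risk score for that setting: a random-forest classifier of 10-year relapse
trained on pooled, normalized microarray cohorts, whose per-patient output —
the **Random Forests Relapse Score (RFRS)** — is the fraction of the
forest's trees voting "relapse".

For training samples the RFRS is computed from **out-of-bag (OOB) votes
only**: each tree is grown on a bootstrap sample (~2/3 of cases), and a
sample's score uses only the trees for which it was out-of-bag. OOB scoring
is an internal cross-validation, so the same cohort yields both the model
and an approximately unbiased estimate of its discrimination (ROC AUC,
computed as the Mann-Whitney probability with ties counted 1/2). The forest
size is odd so a binary vote can never tie; the canonical model uses 100,001
trees, a size chosen for vote-fraction stability rather than accuracy —
2,001 trees give vote fractions stable to roughly one hundredth at
interactive speed, and that is the package default for pipeline runs.

Downstream of the score, the pipeline:

* calls **ER and HER2 status from the arrays** (a designated ER probe; the
  rank-sum of four co-amplified HER2-region probes) with cutoffs fitted by
  two-component Gaussian-mixture EM — the cutoff is the maximum value
  assigned to the lower-mean component, so positivity is strictly
  greater-than;
* assembles an eligible cohort (LN-negative, chemo-naive, HER2-negative by
  array, ER-positive with clinical/array agreement when both exist),
  removes duplicate samples (pairwise Pearson r > 0.99 on log2 profiles,
  transitively closed), binarizes outcomes at ten years, and splits
  two-thirds/one-third balanced on study and outcome;
* filters probes (expressed above raw intensity 100 in at least 20% of
  samples; coefficient of variation between 0.7 and 10, on the linear
  scale);
* compacts the full model into **17-gene-style and 8-gene-style signatures**
  by taking the top 100 genes by Gini importance, k-means clustering them
  (k = 20, then k = 8 on the exclusion-pruned top 90), and keeping each
  cluster's highest-importance gene as the primary with the rest as ranked
  alternates;
* calibrates **risk groups** (3-component mixture on the OOB score
  distribution; scores at a threshold fall in the upper group) and
  population-realistic per-group relapse rates by repeatedly down-sampling
  events to a 15% prevalence; and fits a loess curve mapping RFRS to
  10-year relapse likelihood over 50 score bins, with 95% bands;
* tests group separation by Kaplan-Meier estimation and a **log-rank test
  for linear trend** (1-df chi-square on the score-weighted sum of
  observed-minus-expected events, full hypergeometric covariance).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_trees` | 100,001 (model), 2,001 (pipeline) | forest size; odd, affects vote-fraction stability only |
| `background_threshold` | 100 | linear intensity counted as expressed |
| `min_expressed_fraction` | 0.20 | expressed-sample fraction for probe retention |
| `cov_min`, `cov_max` | 0.7, 10 | linear-scale COV retention band |
| `top_n`, `k` | 100, 20 (8-gene: 90, 8) | compaction pool and cluster count |
| `target_prevalence` | 0.15 | down-sampling target event rate |
| `n_iterations` | 1,000 (200 in pipeline) | down-sampling repetitions |
| `span` | 0.75 | loess span for the likelihood curve |
| `train_fraction` | 2/3 | training share of the split |

## Numerical and design choices

Several points are deliberately fixed where more than one reasonable
convention exists:

* **Mixture fits.** All mixture models are univariate Gaussian with unequal
  variances, fitted by EM. A single deterministic initialization can land in
  a split-bulk local optimum when one component is narrow (the HER2 rank-sum
  distribution is exactly that shape), so EM is restarted from several
  initial partitions — hierarchical-clustering, k-means, equal-count
  quantiles, and a top-tail split — and the highest-log-likelihood fit wins.
  Degenerate inputs where every EM collapses fall back to an exact 2-means
  split only when that split is essentially perfect; otherwise the fit is an
  error advising a manual cutoff. Fits with a component weight below 0.05 or
  component separation under 2 SD are flagged low-confidence.
* **ER cutoff scale.** The ER mixture is fitted on log2 intensities and the
  cutoff back-transformed: within-mode array intensities are approximately
  log-normal, and the positivity call is unchanged by any monotone
  transform.
* **Risk thresholds.** Three mixture components, because there are three
  risk groups; each threshold is the maximum score assigned to the lower
  component, matching the marker-cutoff convention. A quantile (tertile)
  fallback is available behind a flag and is used by the pipeline when the
  mixture degenerates.
* **Down-sampling stopping rule.** Events are removed one at a time until
  the event fraction reaches the target *at the precision targets are
  quoted*: the comparison carries a tolerance of half of one part in a
  thousand (`tol = 5e-4`). A 572-sample cohort with 143 events and a 15%
  target therefore stops at 505 samples / 76 events (76/505 = 15.0%), and a
  toy cohort of 5 events in 10 samples with a 25% target stops after 4
  removals (1 event in 6). A strictly-below-target rule would remove one
  extra event in the first case; the tolerance form reproduces the natural
  "stop at 15%" reading on integer counts.
* **Stratified split rounding.** Largest-remainder allocation across
  (study x class) strata, so the global training share is hit exactly
  whenever possible (858 samples at 2/3 give exactly 572/286); single-member
  strata go to training.
* **k-means.** Gene clustering operates on genes as points in sample space,
  log2-transformed and per-gene z-scored (clustering should group
  co-expression patterns, not absolute levels). Seeding is k-means++ with
  100 restarts: with k = 20 tight clusters, randomly initialized restarts
  reliably merge two planted modules and split another, while D-squared
  seeding recovers the planted partition. Importance ties break
  alphabetically for determinism.
* **Likelihood curve.** The loess fit is tabulated on a fine grid and all
  lookups interpolate that table, so a calibration bundle serializes to
  plain JSON and reloads without any fitted R object. Fitted likelihoods
  and confidence bounds are clamped to [0, 1]; scores outside the fitted
  support take the nearest-endpoint value and are flagged. The curve is fit
  on one seeded down-sampled cohort so its scale reflects the target
  prevalence.
* **Ten-year binarization.** An event *after* ten years counts as
  `no_relapse` (the patient was observed relapse-free through the horizon),
  not as short follow-up.
* **Survival conventions.** Events precede censorings at tied times; trend
  scores are equally spaced 0, 1, 2 (the statistic is invariant to affine
  rescaling of the scores).
* **Cross-platform transfer.** External cohorts are quantile-mapped
  per-sample onto the pooled training distribution, which makes scoring
  invariant to per-sample monotone distortions; risk groups on external
  platforms use training group *proportions* rather than absolute
  thresholds. Where several external probes map to one signature gene, the
  default choice is the highest-variance probe (needs no labels); mean and
  label-based AUC criteria are available and the choice is recorded.

## What the synthetic cohort generator emulates

No public expression data ship with the package; every stage is exercised
against `generate_cohort()`, which draws cohorts with the statistical
structure the pipeline assumes:

* a standard-normal latent prognostic factor per patient, driving relapse
  through a proportional-hazards exponential model (log hazard ratio 0.8
  per SD by default; baseline 10-year event probability 0.25, matching a
  25% training prevalence), with independent exponential censoring
  (0.05/year) and a multiplicative hormone-therapy effect (hazard ratio
  0.7 in the 35.2% treated);
* signal features organized into correlated modules (default 10 blocks over
  50 features): each block factor tracks the latent factor with correlation
  0.6-0.75 and members load on it with one sign per block. The calibration
  (loadings ~1.1, residual log2 noise ~0.7) puts within-module gene-gene
  correlation near 0.7 and the best single gene's univariate AUC near 0.62
  — the regime reported for strong single-gene proliferation markers — so
  within-cluster alternates are genuinely redundant and compaction costs
  little accuracy;
* bimodal marker expression: one ER feature (80% positive) and four
  co-amplified HER2-region features (10% positive) drawn from two-component
  log-normal mixtures;
* log2-scale generation, exponentiated so background sits near intensity 50
  and expressed features in the 200-2,000 range, making the raw-value-100
  background threshold and the COV band meaningful;
* nine studies with additive per-study log2 batch shifts (SD 0.15), injected
  near-duplicates (copy + N(0, 0.01) log2 noise, guaranteeing r > 0.99),
  small LN-positive / chemotherapy-treated / clinically-ER-missing
  fractions so the eligibility filter has work to do, and 2% clinical/array
  ER discordance.

Everything flows from a single integer seed; the same configuration is
byte-identical on regeneration, and all ground truth (latent factor,
duplicate pairs, signal features and their blocks, marker classes) is
recorded.

**What it does not emulate** — and hence what green tests do and do not
show: real platform-specific probe behavior, non-log-normal intensity
distributions, correlated censoring, population structure across studies
beyond an additive shift, or biological pathway overlap between modules.
Recovery results on synthetic cohorts demonstrate that the implementation
recovers what it plants under its own assumptions; they are not evidence
about any specific clinical cohort.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to finish in minutes while
keeping each estimate well-powered: forests of 501-2,001 trees;
recovery cohorts of 400-2,000 samples with 200-1,000 features; 1,000
label permutations for the trend test's size and 100 simulations for its
power; 20-25 down-sampling replicates per calibration seed inside tests
(the package default remains 1,000 iterations). The pipeline-recovery check
draws one 2,000-sample cohort, trains on a 420-sample classifiable subset —
the classifiable yield of a ~600-sample cohort after eligibility filtering —
and evaluates the full and compacted models on the held-out remainder, so
the comparison of the two models has a sharp yardstick instead of a
90-sample test split.

## Known limitations

* The OOB score of a training sample and the de novo score of the same
  sample from the final forest differ by construction; the pipeline follows
  the convention that training samples keep their OOB scores in survival
  analyses and only unseen samples are scored de novo.
* Bit-level equality with other random-forest implementations is not a
  goal; determinism holds within this package under a fixed seed.
* The mixture-based risk thresholds assume the OOB score distribution is
  genuinely tri-modal; on flat score distributions the quantile fallback
  produces tertiles, which is a different (weaker) claim.
* Reference-gene selection implements the stated steps literally, including
  keeping the *top* 10th percentile by standard deviation — atypical for
  reference genes — with a switch (`sd_direction = "bottom"`) for the
  conventional reading.
* `estimate_group_rates()` reports a group's mean over only the iterations
  where the group is nonempty; with extreme thresholds this can bias small
  groups' rates.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(simulation = sim_config(seed = 1), seed = 1)
res <- run_pipeline(cfg, output_dir = "rfrs_run")
res$oob_auc          # OOB discrimination of the full model
res$calibration      # thresholds and prevalence-matched group rates
primary_genes(res$signature)
```
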