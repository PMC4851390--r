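---
title: "Competence classification from follicular-cell expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competence classification from follicular-cell expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ooclassify)
```

## The problem

In IVF treatment, the cumulus cells that surround a retrieved oocyte are
discarded material, yet their transcriptome reflects the follicular
environment in which the oocyte matured. `ooclassify` builds and evaluates
binary classifiers that read a probe-by-sample microarray intensity matrix
from such cells and predict a competence outcome — live birth (LB) versus
no pregnancy (NP) in a training cohort, or blastocyst (B) versus
poor-quality embryo (EP) when a signature is carried to an external cohort
on a different array platform.

The statistical setting is hostile: cohorts of order 10–15 samples per
class, tens of thousands of probes, high within-group variance and small
between-group fold changes. Everything in the package is designed around
the two consequences of that setting: feature selection must happen
*inside* every cross-validation fold (otherwise the error estimate is
badly optimistic), and any apparent signal must be checked against a
permutation null of the whole pipeline.

## The procedure

1. **Pre-filtering.** Probes without functional annotation are removed,
   then probes whose mean intensity across all samples is not strictly
   above a background floor (default 10 on the unlogged scale). Both
   filters ignore the class labels, so they can be applied once, before
   cross-validation, without information leakage.
2. **Nested LOOCV.** For each held-out sample, a two-sample t-test is run
   per probe on the remaining samples only; probes with `p <` the cutoff
   form the fold's feature set; a classifier is trained on the remaining
   samples restricted to that set and applied to the held-out sample.
   Three families are scanned — linear soft-margin SVM, k-nearest
   neighbours, and diagonal linear discriminant analysis (dLDA: LDA with
   per-feature pooled variances and equal priors) — crossed with the
   cutoff grid {0.001, 0.005, 0.01, 0.05}, giving a 12-row model-selection
   table. The winner is the row with maximal LOOCV accuracy; ties go to
   the model with fewer selected features (median across folds), then to
   the algorithm order SVM, kNN, dLDA.
3. **Signature.** Probes passing the chosen cutoff on the *full* data set
   form the deployable signature. Each probe carries its cross-validation
   support: the percentage of LOOCV training folds in which it passed
   selection, a stability weight (a probe never selected in any fold has
   support 0).
4. **Significance.** The whole nested procedure (selection included) is
   re-run on label permutations; the p-value is the proportion of
   permutations with error at or below the observed error.
5. **Probabilities and ROC.** SVM decision values are mapped to class
   probabilities by a Platt-style logistic fit on inner-cross-validated
   decision values; dLDA uses the softmax of its discriminants and kNN its
   vote fraction. `p > 0.5` calls the positive class. The ROC curve over
   the LOOCV probabilities summarises ranking quality.
6. **Cross-platform transfer.** Gene symbols carry the signature to a
   second platform; a gene represented by several redundant probes is
   resolved to the candidate with the *intermediate* mean expression
   (median rank; lower median on even counts), and the resolution is
   logged. A linear SVM trained on the source cohort, with a per-cost
   sweep {1, 2, 10}, is applied to the external samples.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `background_threshold` | 10 (unlogged intensity) | probes at or below this mean are treated as noise-floor measurements |
| `p_grid` | 0.001, 0.005, 0.01, 0.05 | selection cutoffs scanned during model selection (deliberately uncorrected for multiplicity: LOOCV measures the selection's downstream value) |
| `test` | pooled | Student's pooled-variance t-test; Welch behind the flag for unequal variances |
| `k` | 3 | neighbour count; must be odd so a two-class vote cannot tie |
| `cost` / `cost_grid` | 1 / {1, 2, 10} | SVM slack penalty for training / for the external sweep |
| `n_perm` | 1000 | label permutations for the error-rate null |

## Numerical choices and tie-breaks

* **Strictness.** "Mean above background" and "p below cutoff" are strict
  inequalities; a probe with mean exactly 10 is removed.
* **Ties to the negative class.** A dLDA query equidistant from both
  centroids, or any probability of exactly 0.5, is classified negative:
  the package never predicts the favourable outcome on zero evidence.
* **kNN distance ties** at the k-th rank keep the earlier-indexed
  training sample, making predictions deterministic.
* **dLDA variance floor.** Pooled per-feature variances are floored at
  `1e-8` times their mean so constant (background) features cannot
  dominate the discriminant.
* **Zero-variance probes** in both classes get `p = 1` in the t-test: no
  variance, no evidence.
* **Empty-selection folds** (possible on null data at tight cutoffs)
  predict the training-majority class at probability 0.5 and raise a
  warning, so a grid scan on weak data completes instead of aborting.
* **Calibration.** The logistic map is fitted by maximum likelihood with
  a tiny L2 penalty (`1e-6`) on its two parameters, which keeps the slope
  finite under perfectly separated decision values; the slope is
  parameterised negative so probability always increases with the
  decision value. Inner folds are stratified and seeded (3 by default).
* **Permutation p-values** are the plain proportion of nulls at or below
  the observed error (no +1 smoothing; a smoothed variant sits behind the
  `smooth` flag). Each permutation derives its own seed from
  `seed + index`, so single null replicates are independently
  reproducible.
* **Fold change** is the ratio of class means on the unlogged scale,
  signed as `-1/ratio` when below one.

## Design choices where the design was open

* **The t-test variant** is pooled-variance Student by default — the
  classic choice for small-sample microarray class comparison — with
  Welch available.
* **The final signature** is selected on the full data set at the chosen
  cutoff (the model actually deployed), with fold-level support attached
  for stability reading. Alternatives (union or intersection of fold
  selections) are deliberately not the default: they describe the CV
  ensemble, not the deployed model.
* **The cross-platform bridge.** Nothing in a raw intensity scale makes
  an Affymetrix-style training matrix commensurable with another
  platform's intensities. The package imposes per-gene z-scores within
  each data set (after log2-scaling both sides) before applying the SVM.
  This is the package's strongest modelling inference and is deliberately
  prominent: it makes external prediction invariant to any affine
  rescaling of the external platform, which the tests assert.
* **The intermediate-expression rule** is read literally: candidates are
  ranked by mean expression over the external samples and the
  median-ranked probe is chosen, lower median on even counts; the
  resolution log records every candidate so the choice is auditable.
* **dLDA probabilities** are the softmax of the two discriminant values —
  the natural Gaussian-likelihood reading — because a diagonal LDA has no
  canonical probability output.
* **Equal dLDA priors** reflect the near-balanced designs this package
  targets (order 12 vs 15).
* **Interface shape.** The pipeline is exposed as composable R functions
  plus `run_full_pipeline()`; the per-stage functions are the
  "subcommands" (`simulate_study`, `filter_*`, `loocv_grid`,
  `permutation_test`, `roc_curve`, `translate_signature`,
  `external_validate`), each writing plain TSV/JSON artifacts when run
  through the orchestrator.

## What the synthetic generator emulates — and what it does not

`simulate_study()` draws log-normal baseline intensities, multiplies in
mean-preserving log-normal within-class noise at a configured coefficient
of variation, plants `n_de` annotated probes whose positive-class mean is
shifted by `fold_change` (balanced up/down), and reserves configured
fractions of probes as unannotated or below background. The defaults —
12 vs 15 samples, 20,000 probes, 15% unannotated, 10% background, 30
planted probes at fold change 4, CV 0.3 — mirror the shape of a small
follicular-cell cohort with a recoverable but not trivial signal.
`simulate_external_platform()` re-draws a cohort from the same effect
model on a second platform with symbol-level annotation, 1–3 redundant
probes per gene with log-normal affinity multipliers, a dropped gene
fraction (default 1/6), a different global intensity scale, and a log2
transform.

The generator does **not** emulate probe-level hybridisation physics,
batch or dye effects, correlated gene modules, or heavy-tailed outlier
samples. Passing tests therefore demonstrate that the *machinery* is
correct and honest (no selection leakage, calibrated permutation null,
recoverable planted signal, working cross-platform transfer) — not that
any particular biological cohort contains a signal.

## Problem sizes used by the test suite

The statistical property checks run at deliberately reduced scale chosen
to keep the suite quick while leaving the conclusions unchanged:
leakage and null-calibration checks use 2,000- and 400-probe matrices
(the leakage contrast and p-value uniformity are scale-free properties of
the procedure), the recovery check runs one full 20,000-probe study, and
the permutation-uniformity check uses 50 replicates of 200 permutations
on 8 vs 8 cohorts.

## A worked example

```{r example, eval = FALSE}
library(ooclassify)

cfg <- simulation_config(seed = 1)
sim <- simulate_study(cfg)
ext <- simulate_external_platform(sim, cfg)

report <- run_full_pipeline(pipeline_config(
  expr = sim$expr, annot = sim$annot, labels = sim$labels,
  external = list(part1 = ext),
  n_perm = 1000, seed = 1
))
report
glance(report$cv)
autoplot(report$roc)
plot_probabilities(report$cv)
plot_cv_support(report$signature)
```

## Known limitations

* LOOCV on cohorts this small has high variance, and on pure-noise data
  its accuracy is slightly *pessimistic* (the held-out sample's class is
  under-represented in training); the permutation test, which compares
  like with like, is the trustworthy significance statement.
* The permutation null of the LOOCV error is heavy-tailed when probes
  vastly outnumber samples: in roughly one permutation per thousand the
  chance false positives of the selection step align with the permuted
  labeling across the whole cohort and reach zero cross-validated error.
  An observed zero error therefore earns a permutation p of about 0.001,
  not 0 — which is exactly why significance is read from the permutation
  test rather than from the error rate alone.
* The z-score bridge assumes each gene's distribution is comparable
  across cohorts after location/scale adjustment; platform-specific probe
  behaviour that changes a gene's rank ordering will degrade transfer.
* Matrices must be complete; the package deliberately refuses missing
  values rather than imputing.
* Only binary endpoints are supported.
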