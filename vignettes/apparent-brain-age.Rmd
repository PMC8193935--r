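---
title: "Classification-biased apparent brain age: model, pipeline and design notes"
author: "ApparentAge package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification-biased apparent brain age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Brain-age biomarkers predict a subject's age from structural-MRI
morphometry and read the gap between predicted and chronological age as a
sign of accelerated neuroanatomical ageing. Classical brain-age models
(BrainAGE and its successors) are trained to track chronological age as
closely as possible over the whole brain. This package implements a
different estimator, the *Apparent Brain Age* (ABA): the age regression is
deliberately restricted to a small subset of morphometric features chosen
because they discriminate Alzheimer's disease (AD) from cognitively normal
(CN) subjects. The regression is trained on CN subjects only, so for an AD
subject the selected regions "look older" than the subject is and the ABA
over-estimates age. The ABA is therefore not an estimate of the biological
age of the whole brain; it is a classification-oriented biomarker defined
over a few automatically selected regions of interest (ROIs).

The model chain is linear end to end, which is what makes it explainable:

1. **Standardization.** Each feature is z-scored with moments estimated on
   the training partition only (unbiased, n-1 denominator). Age is never
   standardized, so regression errors stay in years.
2. **Outlier removal.** An isolation forest (sub-sample size psi = 256,
   height limit 8, 100 trees) scores every record; records whose score
   strictly exceeds the Tukey fence `Q3 + 3*IQR` of the *training* scores
   are removed from training and excluded from test metrics (and listed
   separately). Labels are never used.
3. **Feature ranking and biased forward selection (FFS).** Features are
   ranked by the absolute point-biserial correlation with the AD/CN label.
   A forward wrapper walks the ranked list; each candidate subset is scored
   by inner stratified cross-validation of the *downstream classification
   accuracy* (not the regression error) and kept only if it improves it.
   The wrapper output is the subset F1.
4. **Sparse age regression.** A LASSO regression of chronological age on
   the offered features, fitted on CN training subjects only:
   `aba = a0 + sum_i a_i * f_i`. The nonzero support is F2, with
   F2 ⊆ F1 ⊆ F. The Age Deviation Score is `ads = aba - age`.
5. **Classification.** A logistic model on the two inputs (age, aba);
   with the stored sign convention a subject is AD when
   `c0 + c1*age + c2*aba < 0` (ties go to CN).
6. **Per-feature explanation.** Substituting the ABA equation into the
   boundary gives each support feature a score
   `s_i = -c2 * a_i * f_i / D` with `D = c0 + c1*age + c2*a0`, and the
   boundary value factorizes as `D * (1 - sum(s_i))`. The score sum
   reproduces the classification decision exactly whenever `D != 0`:
   AD iff `sum(s_i) > 1` when `D > 0`, and iff `sum(s_i) < 1` when
   `D < 0`. Test subjects are read against the AD and CN quartile boxes of
   the training scores.

On the sign of the score-sum rule: written as a single printed inequality
the rule needs an assumption on the sign of `D`, and the two printed forms
(the `> 1` rule and the sign assumption on the denominator) are mutually
consistent only for one sign. The implementation does not trust either
printed direction; it derives the comparison direction from the runtime
sign of `D`, which makes the decomposition *algebraically identical* to the
logistic boundary — an identity the test suite checks exhaustively on
randomized models.

## Leakage control

Every fitted object — standardization moments, the isolation forest and its
cutoff, the ranking, the wrapper selection, the LASSO, the logistic
coefficients — depends on the training partition of the current fold only.
The wrapper's inner cross-validation re-partitions the outer training set.
The suite enforces this mechanically: test-fold features, ages and labels
are perturbed and every fitted sub-model must be unchanged.

## Evaluation protocol

`repeatedCV()` runs stratified k-fold cross-validation repeated R times
(the study design is 10 x 10; the packaged tests use 2 x 5 on the n = 1000
fixture to keep a full run inside a few minutes on one CPU). Metrics are
pooled within a repeat — one confusion matrix per repeat — and the mean and
SD are taken across repeats. AD is the positive class; accuracy, AD recall
and AD precision are reported in percent, MAE in years and Pearson r per
diagnostic group. `holdout()` (default 80-20%) additionally emits the
per-subject feature-score reports and training quartile context;
`crossCohort()` trains on one cohort tag and tests on another, mixed
genders allowed. The M5 ablation skips the wrapper and offers all features
to the LASSO; M4 of the study design is M5 on a restricted training cohort.

## The synthetic cohort generator

Real ADNI/AIBL/IXI feature tables are access-controlled, so the package
ships a generator that emulates their structure and provides ground truth:

* **Demographics.** `table1Strata()` reproduces the study population's
  gender x cohort x group counts and per-stratum age moments and ranges
  (1,901 subjects; 861 male, 1,040 female; IXI contributes CN only). Ages
  are truncated-normal per stratum.
* **Feature law.** Linear-Gaussian: an informative feature is
  `baseline - slope * effectiveAge + noise`, where AD subjects age an
  extra `acceleration` years (default 8) — the generative mirror of the
  ABA over-estimation narrative. Ageing-only features decline with
  chronological age but carry no AD signal; noise features carry neither.
  Every downstream model is linear, so parameter recovery is analyzable
  and an exact Bayes reference posterior exists (`bayesReference()`),
  whose accuracy upper-bounds any pipeline on the same data.
* **Default scales.** Informative ROIs: baseline 4000 units, slope 20
  units/year, residual sd 135 — hippocampal-volume-like numbers giving a
  per-feature AD effect of d ≈ 1.2, in the range reported for medial
  temporal structures. The default evaluation fixture
  (`defaultFixtureConfig()`) is a 1,000-subject single-gender cohort with
  5 informative, 20 ageing-only and 75 noise features. The ageing-only
  block exists so the M5/M6 contrast is observable: offering all features
  improves the CN age fit (higher r) while diluting the AD signal in ABA,
  exactly the pattern the method is designed to exploit.
* **Outliers.** Planted by inflating a random subject's whole feature
  vector by `outlierMagnitude` (default 6) residual standard deviations
  with random signs — corrupt-record-like, not label noise.

What the generator does *not* emulate: inter-feature correlation within a
subject (real ROI volumes are strongly correlated), site/scanner batch
effects, heteroscedastic ageing, non-linear decline, and MCI or
longitudinal structure. Passing tests on this fixture therefore show that
the pipeline recovers a planted linear-Gaussian signal near its Bayes
bound, not that it attains any particular accuracy on clinical data.

## Numerical and design choices

* **Quantiles** everywhere (Tukey fence, score quartile boxes) use linear
  interpolation between order statistics (`stats::quantile` type 7); the
  cutoff rule depends on the convention, so it is fixed and documented.
* **Strict inequality at the fence**: a record exactly at the cutoff is
  kept.
* **Isolation-forest path lengths** extend truncated or multi-point leaves
  by the standard average-path correction c(size), so scores are
  comparable across tree depths and lie in (0, 1].
* **FFS acceptance threshold.** The wrapper keeps a candidate only when
  mean inner-CV accuracy improves by more than one validation subject
  (epsilon = 1/n). A gain of exactly one re-classified subject is the
  resolution of the accuracy estimate; accepting it (epsilon = 0) admits a
  steady trickle of noise features whose whole contribution is one lucky
  subject, which measurably degrades recovery of the planted informative
  set. epsilon remains configurable, including 0. The top-ranked feature
  is always retained so the age model is never featureless; one pass, no
  backtracking.
* **LASSO penalty.** "auto" selects the penalty by 5-fold cross-validated
  MAE on the CN training set over a logarithmic grid; the intercept is
  unpenalized (so the infinite-penalty limit is the CN mean age). Inside
  the wrapper a fixed light penalty (0.1 on z-scored features) is used for
  speed and stability of the inner comparison.
* **Separation fallback.** Perfect separation of the 2-D logistic problem
  falls back to a small ridge penalty (IRLS, lambda = 1e-3 on the
  non-intercept terms) with a warning.
* **Boundary ties are CN** (score exactly 0, or score sum exactly 1):
  conservative for a screening biomarker.
* **Single standardization step** per fold, fitted on all training rows
  (not refitted on CN only before the regression).
* **Missing values are rejected, not imputed**; the upstream cleaning is
  assumed to have handled erroneous features. ICV is not treated specially
  and no ICV normalisation is performed.
* **Determinism.** All randomness flows from one master seed expanded per
  stage/repeat/fold; identical seeds give identical tables, forests, folds
  and models. Model JSON is written with 17 significant digits so a
  serialization round trip reproduces predictions bit-exactly.

## Known limitations

The wrapper's inner criterion is noisy at small n; with fewer than a few
hundred training subjects the selected set F1 varies across folds (the
selection-frequency report exists precisely to summarize that variation).
Exactly collinear features make the LASSO split of shared weight
non-unique; the fitted support may then carry a knife-edge duplicate with
negligible weight. ABA should not be read as an estimate of whole-brain
biological age, and the linear model chain trades away any non-linear
accuracy gains for explainability.
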