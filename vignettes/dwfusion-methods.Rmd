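---
title: "Dynamic weighted fusion: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic weighted fusion: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Platinum resistance in ovarian cancer is diagnosed retrospectively, from
the platinum-free interval (PFI): patients relapsing within 6 months of
their last platinum dose are resistant, those relapsing at 12 months or
later are sensitive. dwfusion treats resistance prediction as binary,
imbalanced classification from routine pre-treatment laboratory values —
about a 2:5 minority:majority ratio in the motivating setting — where no
single marker is strongly predictive and the useful signal is spread over
correlated blocks of weakly informative features.

The model is a *dynamic* ensemble: instead of one fixed committee, each
outer cross-validation fold re-ranks a large grid of base classifiers and
fuses the locally best ones.

1. **Grid.** Every enabled feature selector is crossed with every enabled
   learner (14 × 12 = 168 cells at defaults). A cell selects the top
   `top_k_features` (10) features on the fold's training data, then tunes
   and fits its learner on those features.
2. **Screening.** Cells are ranked on the fold's validation data by the
   G-mean, `sqrt(sensitivity * specificity)` at threshold 0.5 — chosen over
   accuracy because it cannot be gamed by majority-class guessing.
3. **Weighting.** The best `top_n_classifiers` (10) cells receive a
   combined score `CS = 0.6 AUC + 0.4 G-mean` and softmax weights
   `exp(CS_i/T) / sum_j exp(CS_j/T)` with temperature `T = 0.1`. At this
   temperature a CS advantage of 0.1 multiplies a cell's weight by
   `e ≈ 2.7`: weight concentrates sharply on the best cells while all ten
   retain a positive contribution.
4. **Fusion and thresholding.** The fused score is the weighted average of
   the cells' class-1 probabilities. The final decision threshold
   maximizes the G-mean of the fused validation scores, because 0.5 is
   systematically miscalibrated after minority oversampling.

### An assumption worth stating

The published procedure ranks, weights *and* evaluates the cells on the
same validation fold. The reported cross-validation metrics therefore
carry an optimistic selection bias. The default reproduces that procedure
faithfully; `dwf_control(honest_selection = TRUE)` instead carves a 20%
tuning slice out of each training split for ranking/weighting/thresholding
and keeps the validation fold untouched. We deliberately default to the
faithful variant: the package's first job is to reproduce the method as
specified.

## Preprocessing (fit on training folds only)

Four steps, in order, with every statistic learned from the training split
and merely *applied* to validation rows:

* **Reference-range capping** — values above a feature's standard upper
  limit are truncated to it. Limits are user-supplied configuration
  (JSON/CSV); no public reference-range table accompanies the motivating
  study, and `synthetic_reference_ranges()` provides a synthetic stand-in
  (97.5th percentile of the sensitive class).
* **Chained-equation imputation** — each incomplete feature is repeatedly
  regressed on all others (ridge stabilizer 1e-3, which only matters on
  near-collinear panels), initialized at observed means, for at most 30
  sweeps or until the largest imputed-cell change falls below 1e-3 of the
  feature's observed SD. `apply()` runs a fixed sweep count so each row's
  completion is independent of which other rows are in the batch.
* **Box–Cox** — per feature, a positivity shift `max(0, 1e-6 - min)` and a
  power `lambda` maximizing the profile likelihood over `[-5, 5]`
  (`stats::optimize`, tolerance 1e-5). Constant features get `lambda = 1`.
  Whether the transform covers all features or only a named subset is a
  config switch (`boxcox_features`); the default is all, since the
  skewness argument is not restricted to tumor markers.
* **Min-max scaling** to `[0, 1]` on the training range; out-of-range
  validation values are clipped. Bounded inputs protect the
  distance-based learners (KNN, SVM, SMOTE's neighbor searches).

## Oversampling

Borderline-SMOTE (borderline-1): a minority point is DANGER when at least
`m/2` but fewer than `m` of its `m = 5` nearest neighbors (all classes)
are majority; pure-majority neighborhoods are treated as noise and
skipped. Synthesis interpolates toward one of the point's `k = 5` nearest
*minority* neighbors with Uniform(0,1) coefficients until the 1:1 target
ratio is met. `m`, `k` and the ratio are the algorithm's common defaults —
the motivating description names none. Neighbor ties break by row index;
the synthesis stream is seeded, so output is bit-reproducible. A leakage
audit (`guard_no_leakage()`) runs inside every fit and aborts if any
synthetic parent falls outside its training split.

Selection order: selectors score the *oversampled* training set by
default, keeping one consistent training view for selection and fitting
(`select_before_oversample = TRUE` flips this; the method description is
silent on the order).

## Selectors and learners

Filter selectors (ANOVA F, Welch t, Fisher score, Laplacian score with a
5-NN heat-kernel graph, reliefF with 10 hits/misses, and the
mutual-information family JMI/DISR/ICAP via greedy forward selection on
5-bin equal-frequency discretized features) are implemented from their
textbook formulas and verified against longhand oracles in the tests. The
sparse-learning selectors follow their published iterative algorithms:
trace-ratio with LDA scatter graphs; MCFS (spectral embedding + per-
eigenvector l1 fits); NDFS and UDFS (l2,1-reweighted iterations on 5-NN
graph embeddings, deterministic spectral initialization). LS_l21 is the
convex least-squares-loss + l2,1-penalty program solved by
majorize-minimize ridge steps — the fully "robust" variant with an l2,1
loss as well oscillates on one-hot targets and is not used. LL_l21 is the
logistic counterpart via IRLS with a majorized penalty. Greedy and
ranking ties break by feature index; a method whose native score is
"smaller is better" is negated so larger always means more relevant.

Learners ride on the field's standard engines where one exists — glmnet
(ridge logistic), rpart, ranger (RF, extra trees, class-balanced RF),
e1071 (RBF SVM), xgboost (depthwise gradient boosting; regularized
boosting; leaf-wise `lossguide` histogram boosting) — and two are native
implementations: SAMME AdaBoost over rpart trees, and oblivious-tree
(symmetric) gradient boosting with histogram split search, the tree family
CatBoost popularized for purely numeric tabular data. The SVM's
probabilities come from our own Platt-style sigmoid fitted on seeded
inner-fold decision values, because libsvm's built-in probability CV is
not seedable from R and would break run-to-run determinism. KNN
probabilities are the mean neighbor label with index tie-breaks for the
same reason.

Hyperparameters are tuned by randomized search (20 draws at default) under
a stratified internal 3-fold CV scored by mean G-mean at threshold 0.5 —
the same metric the framework uses for screening. Search spaces are small
standard ranges (tree depth 2–10, 50–300 estimators, learning rates
10^-3–10^0.5 log-uniform, SVM C in 10^±2 and gamma in 10^[-3,1], KNN k in
3–15, ridge strength 10^[-3,2]); none are specified by the method's
source, so they are package defaults exposed through `dwf_control()`.

## Randomness and determinism

One master seed drives everything. Each stochastic stage (fold split,
SMOTE, tuning draws, stochastic fits, cohort generation) derives its own
stream via a fixed integer hash of (master seed, stage, fold, cell), and
all seeded evaluation restores the caller's RNG state. Two fits with the
same seed and inputs produce identical cell metrics, weights, thresholds
and pooled scores; the test suite asserts this.

## Degenerate inputs and tie-breaks

* Grids smaller than `top_n_classifiers` fuse all available cells with a
  warning. Failed cells are logged and excluded rather than fatal.
* Cell ranking ties break by higher AUC, then selector/learner id;
  softmax ties keep the ordering of the combined scores.
* Threshold candidates are midpoints between consecutive distinct fused
  scores plus guards below/above the extremes, restricted to (0, 1); ties
  take the smallest threshold.
* Zero-denominator metrics (empty subgroup cells) return flagged `NA`,
  never an error; single-class inputs error early with a clear message.
* Constant features: Box-Cox `lambda = 1`, min-max maps to 0, Fisher/t/F
  scores 0.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of the motivating cohort, not
its values: 322 patients (91 resistant / 231 sensitive, exact counts), 70
features in five correlated blocks (clinical, blood count, liver/renal,
tumor markers, coagulation) with latent within-block correlation 0.5 and
between-block 0.1; lognormal marginals for the eight tumor markers, FDP
and D-dimer; 1.62% of feature cells missing completely at random (the
outcome is never missing); and standardized latent shifts in the resistant
class — Age +0.45, NL/GRAN +0.35, GRAN#/FIB/FDP +0.30, WBC/UREA +0.25,
LYM −0.30. Directions follow the reported group differences; magnitudes
are calibration choices placing single-feature discrimination in the weak
univariable regime (AUC ≈ 0.60) that the motivating data exhibit, and are
documented as such, not as ground truth. Marginal locations and scales are
plausible clinical values chosen once.

What passing tests on this generator do *not* show: real laboratory data
have non-Gaussian dependence (e.g. hard physiological bounds, ratio
features algebraically tied to their components, informative missingness),
and none of that is emulated. End-to-end results on synthetic cohorts
demonstrate that the machinery behaves as specified — not that the
clinical performance of the motivating study transfers.

## Problem sizes used by the automated checks

The test suite runs the full pipeline at reduced scale, chosen as the
smallest sizes that still exercise every code path: the end-to-end
comparison uses the default 322 × 70 cohort with a restricted 4 × 4 grid
(the four cheapest selectors × four cheapest learners, picked up front for
speed) and 5 search draws over 5 seeds; leakage probes run on a 200 × 20
subset with a 2 × 2 grid. The acceptance script regenerates the default
cohort under 20 seeds. Full-grid fits at default settings are intended
for real analyses, not the test suite.

## Known limitations

* The faithful default inherits the optimistic fold-reuse of the original
  procedure; use `honest_selection = TRUE` for unbiased estimates.
* Deployment prediction (equal-weight averaging of the five fold
  ensembles and thresholds) is a package convention — the method's source
  defines only cross-validated evaluation.
* Calibration of the fused scores is not addressed (no Platt/isotonic on
  the fusion output); θ_opt corrects the operating point, not the score
  scale.
* The univariable report uses Wald intervals, which degrade under
  separation; affected features are flagged rather than refit.
* Multi-class extension to partially platinum-sensitive patients is out of
  scope by design.
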