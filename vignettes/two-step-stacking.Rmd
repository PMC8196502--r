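---
title: "Two-step stacking for echocardiography-based CHD screening: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step stacking for echocardiography-based CHD screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echostack)
```

## The screening problem

Coronary heart disease (CHD) is conventionally confirmed by angiography,
an invasive and costly procedure. Two-dimensional speckle-tracking
echocardiography (2D-STE) offers a non-invasive alternative signal:
myocardial deformation ("strain") degrades early in ischemia, and
longitudinally oriented sub-endocardial fibers degrade first. `echostack`
implements a screening classifier that maps 64 strain-derived features
plus 7 clinical risk factors to a binary CHD prediction.

The 71 predictors follow a fixed schema (`feature_schema()`): three
17-segment blocks over the AHA 17-segment left-ventricular model — peak
systolic strain (PSS, %), systolic strain rate (SSR, 1/s) and time to
peak strain (TP, ms) — nine radial global-strain features (mitral-valve,
papillary-muscle and apical levels by endo/mid/epi layer), layer-specific
global longitudinal peak strain (GLPS, 3 features), the peak standard
deviation of time-to-peak (PSD), and age plus six binary risk factors
(gender, hypertension, diabetes, hyperlipemia, smoking, family history).
Tables are read from CSV; `Y/N` and `M/F` codings are normalized to 1/0;
missing values are a validation error rather than being silently imputed,
because imputation would change the estimator being evaluated.

## The two-step stacking estimator

With $L$ fitted classifiers each voting $c_l \in \{0, 1\}$ on a subject,
majority voting returns $1(\tfrac{1}{L}\sum_l c_l \ge 0.5)$ and weighted
voting returns $1(\sum_l w_l c_l \ge 0.5)$. Stacking generalizes the
weights to a second-level learner trained on the base classifiers'
held-out-validation predictions; the "weights" are then an arbitrary
learned function and need not be non-negative. Throughout the package the
$\ge$ in these indicators is taken literally: a score of exactly 0.5
classifies as positive.

The two-step estimator repeats first-level stacking over $K$ resampled
splits of the training pool and stacks the stacks:

1. Hold out a testing set (15% of subjects) and a second-step validation
   set ("validation 0", 20% of the remainder). With 424 subjects split
   217/207 this gives 64 / 72 / 288 subjects.
2. For $k = 1, \dots, K$: draw a stratified split of the 288-subject pool
   into 230 training and 58 validation subjects; fit the $L$ base
   classifiers on the 230 and a meta-learner on their hard-label
   predictions over the 58.
3. The $K$ stack outputs on validation 0 form a $72 \times K$ binary
   matrix on which a second meta-learner is fitted against the
   validation-0 labels.

Defaults are $L = 14$, $K = 10$. Test subjects are never touched during
any fitting stage, and `fit_stack()` refuses overlapping train/validation
subject ids outright.

Both meta-learners are random forests (`randomForest`, 500 trees,
stratified within-class bootstrap), with the ensemble score defined as
the fraction of trees voting positive. Because the first-step validation
sets hold only 58 subjects, the meta forest's terminal node size scales
with the validation sample (`nodesize = n/5`): with fully grown trees the
meta-learner memorizes individual validation subjects' vote patterns and
each stack generalizes worse than its own base classifiers, whereas
leaves of about a fifth of the sample average over neighbouring vote
patterns and behave like a locally adaptive weighted vote. Meta-learners
see hard 0/1 base predictions by default, matching the vote-based
formulation above; `stack_on = "score"` feeds base-classifier scores
instead, a common stronger variant that is deliberately not the default.

Whether the $K$ first-step splits should form a partition family or be
resampled independently is an open design point; the package resamples
independently (each split is a fresh stratified draw), which keeps $K$
free of divisibility constraints.

## Base classifier registry and the 60% rule

`list_registry()` declares 19 classifier families behind one
fit/predict contract (`fit_classifier()`, `predict_labels()`,
`predict_scores()`). Method-family names are the interface; each adapter
delegates to an established backend (glm, glmnet, randomForest, ranger,
e1071, kernlab, MASS, class, nnet, xgboost). Four families deserve a
note:

* *Cumulative probability model*: for a binary outcome the
  cumulative-link likelihood coincides with logistic regression, and it
  is fitted as such.
* *Sparsed LDA*: fitted by lasso-penalized optimal scoring; with two
  classes, optimal scoring reduces to a penalized regression on a
  centered class indicator, followed by a one-dimensional logistic
  calibration of the discriminant score.
* *Bayes generalized linear model*: logistic regression under a Gaussian
  coefficient prior, i.e. ridge-penalized logistic regression.
* *Monotone multi-layer perceptron*: a single-hidden-layer network whose
  two weight layers are constrained non-negative through a softplus
  parameterization, making the fitted score non-decreasing in every
  standardized input; trained by BFGS on the cross-entropy with analytic
  gradients.

Hyperparameter grids are small (at most 3 configurations) and tuned by
stratified 5-fold cross-validated accuracy on the training subjects only;
single-configuration families skip tuning. All stochastic fits derive
their seeds from the configuration seed by fixed offsets, so a fitted
ensemble is reproducible bit-for-bit.

Ensembling is preceded by a screening rule (`filter_by_accuracy()`):
families whose benchmark accuracy falls below 60% are excluded. Applied
to the published benchmark accuracies shipped as
`chd_benchmark_accuracies()`, the rule removes random forest, weighted
subspace random forest, K-nearest neighbor, sparsed LDA and stochastic
gradient boosting, leaving the default 14-family roster
(`default_ensemble_specs()`). Screening on test-set accuracy, as the
benchmark did, leaks information from the evaluation split; the package
therefore treats the resulting roster as a fixed design input rather than
re-screening per run.

## Preprocessing

**Univariate screen.** `ttest_screen()` applies a two-sided two-sample
t-test per feature, Welch's unequal-variance variant by default (the
pooled test is a flag away), flagging $p \le 0.05$. The screen is
descriptive — no features are dropped. Features with zero variance in
both classes report $t = 0$, $p = 1$ with a degeneracy flag rather than
erroring. Group-level p-values (as in `effect_pattern_check()`) are
computed by a t-test on the within-group mean feature, which pools the
correlated segment signals; this explains why a group p-value can be
smaller than every per-feature p-value in the group. No multiple-testing
correction is applied, matching how such screens are conventionally
reported for this feature set.

**Block PCA.** The three 17-segment blocks are individually reduced by
principal components (`fit_block_pca()`), fitted on training subjects
only and applied to held-out subjects by projection. Correlation-matrix
PCA (center and scale) is the default because the blocks live on
different measurement scales; covariance PCA is available. Component
counts come from `choose_components()`: the `fixed` rule retains 3/3/2
components for PSS/SSR/TP (the counts chosen from scree-plot elbows for
this feature set), and the `elbow` rule computes
$\arg\max_j \lambda_j / \lambda_{j+1}$. Loading-column signs are fixed by
making each column's largest-magnitude element positive, so fitted
models are byte-stable. The default reduction takes 71 predictors to
$71 - 51 + 8 = 28$.

**Splits.** `make_split_plan()` allocates per-stratum counts by
round-half-up on `stratum_n * frac`, reconciled to the round-half-up
total by adjusting the stratum with the largest rounding residual (ties
to the larger stratum). This reproduces the canonical arithmetic
(424 × 0.15 → 64 with 33/31 by class; 288 × 0.20 → 58 with 30/28) while
keeping every part within one subject per class of the stratified
target. First-step sub-splits are stratified as well.

## The synthetic cohort generator

`generate_cohort()` exists so that every pipeline stage is testable
without access to any clinical data. It emulates three things:

* **Clinical marginals** of a suspected-CHD referral cohort: age
  per class (64.39 ± 9.79 vs 64.11 ± 9.52 years) and per-class
  prevalences of the six binary risk factors, of which only smoking
  differs materially between classes (52.5% vs 28%).
* **Block correlation structure** among the strain features, as a
  two-level design: apical segments (AHA 13–17) highly correlated,
  basal/mid segments moderately, a weaker between-group term; PSS and
  SSR coupled; TP more uniformly correlated than either and only weakly
  coupled to them; radial features weakly correlated across levels;
  GLPS layers strongly correlated. The full 64 × 64 correlation matrix
  is validated by Cholesky factorization at construction — an
  inconsistent configuration errors, it is never projected or repaired.
* **Class effects** as standardized mean shifts per feature group.
  Defaults (GLPS 0.30, PSS 0.22, SSR 0.20, TP 0.13, PSD and radial 0)
  are *calibrated, not measured*: they are back-solved from the
  qualitative significance pattern such screens report at n = 424 —
  GLPS strongly significant, PSS/SSR significant, TP borderline, PSD
  and the radial sections not — via $d = 2 z_p / \sqrt{n}$. They are
  parameters of the simulation, not claims about any real cohort.

Labels are assigned by exact count (`round(n × prevalence)`, default
217/424) rather than per-subject coin flips, making split sizes
deterministic. Gaussianity of the strain features is an explicit
modelling choice: it makes the t-screen and PCA exactly analyzable.
What the generator does **not** emulate — measurement noise from image
quality, vendor differences, non-Gaussian tails, missingness,
nonlinear feature/outcome links — bounds what passing tests show: they
validate the pipeline's mechanics and its behaviour under a known
correlation/effect structure, not clinical performance. Headline
accuracies from the real cohort this design comes from (87.7% accuracy,
AUC 0.904) depend on a non-public training set and are not reproducible
from this package.

## Evaluation protocol

`run_replicates()` redraws the *entire* split plan per replicate (test
set included) with seed `base_seed + r`, runs every requested method on
identical splits (a paired design, which only sharpens method
contrasts), and reports mean ± SD (n−1) of accuracy, AUC, sensitivity
and specificity over replicates. Redrawing everything is the only
reading under which the standard deviation of test accuracy across
replicates is meaningful. ROC curves use ensemble scores, not hard
labels, so they have more than three points; AUC comes from the
trapezoidal rule (pROC) and equals the tie-adjusted concordance
probability. Weighted voting uses non-negative weights proportional to
validation-0 accuracy, normalized to sum to one — the benchmark does not
specify its weighting, and this choice keeps the vote score inside
[0, 1]. The GLPS-only ablation (`glps_only_run()`) restricts predictors
to the three GLPS layers with no PCA and runs the identical two-step
protocol.

Problem sizes used by the shipped checks were chosen to keep a full
desk-scale analysis comfortable on a single CPU: generator-fidelity
checks run at n = 10,000, oracle-equivalence suites at n ≤ 50 per
instance, and the replicated method comparison at the study scale
(n = 424, L = 14, K = 10) with R = 20 replicates in the test suite and
R = 5 in the acceptance script.

## Numerical and degenerate-input conventions

* Ties at a score of exactly 0.5 classify positive, everywhere.
* Zero-variance features: error in scaled PCA (a flag disables
  scaling), degeneracy flag in the t-screen, variance clamped to 1 in
  classifier standardization.
* Tuning ties take the first grid row, making tuning deterministic.
* `filter_by_accuracy()` retains at the boundary (accuracy ≥ threshold).
* Empty classes, overlapping split parts, K/config mismatches and
  schema mismatches are errors, not warnings.

## Known limitations

* The generator's Gaussian, linear-shift model cannot probe calibration
  or threshold choice under realistic miscalibration.
* The monotone MLP assumes monotonicity in *all* standardized inputs,
  which is stronger than monotonicity in selected covariates.
* Probability outputs of the SVM adapters are logistic transforms of
  decision values, adequate for ranking (ROC) but not calibrated.
* With 1 subject per stratum in a part, stratified proportions are
  necessarily coarse; `make_split_plan()` errors rather than silently
  unbalancing when a stratum cannot populate every part.
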