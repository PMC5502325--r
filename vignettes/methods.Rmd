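---
title: "Causal feature selection and nested cross-validated risk prediction with mbrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal feature selection and nested cross-validated risk prediction with mbrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`mbrisk` implements a complete analysis protocol for a hard but common
epidemiological setting: predicting a *rare* binary clinical outcome (a
case rate around 7%) from a *wide* table of acute-phase measurements
(around 105 mixed binary/ordinal/continuous variables) observed on a
*small* cohort (around 163 subjects), with substantial missingness. The
motivating application is predicting which injured children will meet a
post-traumatic stress disorder symptom threshold (a symptom-scale score of
38 or greater, assessed months later) from variables collected during the
acute hospitalization. Nothing in the machinery is specific to that
outcome: any cohort table with a dichotomized target fits.

Two questions are asked of such data:

1. **Predictivity** — how accurately can the outcome be predicted, measured
   honestly (no information from a subject's own data may leak into the
   model that scores that subject)?
2. **Candidate causes** — which small set of variables carries all the
   non-redundant predictive information, and is therefore the natural
   candidate set for mechanisms and intervention?

## The pieces

### Preprocessing

Variables missing *strictly more than* 50% of entries are removed (the
fraction is configurable; a variable at exactly the threshold is kept).
Remaining missing cells are filled by unsupervised k-nearest-neighbour
imputation: for each subject with missing entries, donor subjects are
ranked by Euclidean distance over mutually observed coordinates (scaled by
the overlap size), and each missing cell takes the plain mean of the k
nearest donors observing that variable (`k = 10` by default; the method
cited by the protocol does not fix k, and results are insensitive within
5–20 at these dimensions). Binary and categorical imputations are rounded
to the nearest legal level so discrete-data tests downstream remain valid.
The outcome is never an input to imputation. Finally each variable is
mapped to [0, 1] by min–max normalization. Inside cross-validation the
donor pool and the normalization bounds come from the training fold only,
and held-out values are deliberately *not* clipped to [0, 1] — clipping
would use the information that a test value is extreme.

The order filter → impute → normalize, and the refitting of
imputation/normalization per training fold, are choices the protocol
description leaves open; both are configurable and are logged.

### Conditional-independence tests

The feature-selection algorithm consumes a conditional-independence (CI)
primitive. Two standard instantiations are provided:

* **Fisher-z** (default): the z-test on the partial correlation of x and y
  given Z, computed from the inverse of the correlation submatrix;
  discrete variables enter numerically after 0–1 normalization. Effective
  sample size is n − |Z| − 3; below 10 the test is flagged unreliable.
* **G²**: the likelihood-ratio test on contingency tables with
  dof = (|x|−1)(|y|−1)·∏|z|; continuous variables are median-split first.
  A conditioning stratum whose average expected cell count falls below 5
  flags the test unreliable.

An *unreliable test never rejects independence*: at n ≈ 163 a misleading
rejection would wrongly eliminate a variable, so the conservative reading
is standard practice in constraint-based discovery. The significance level
alpha defaults to 0.05 everywhere.

### Semi-interleaved HITON-PC (without symmetry correction)

`run_hiton_pc()` estimates the target's *parents and children* (PC) set —
its direct causes and effects. Candidates are admitted in order of
univariate association strength; as each is admitted, it is tested against
the target conditioned on every subset (size ≤ `max_k`, default 3) of the
current tentative set, and permanently discarded with the first separating
subset as witness if any renders it independent; a final backward pass
re-screens all survivors. The reciprocal-membership (symmetry) check is
omitted. Ties in the admission ordering break by p-value, then |statistic|,
then name, so output is deterministic.

When the target is *terminal* — it has no downstream effects, as holds for
an outcome measured after all predictors — the PC set has no children or
spouses, so it coincides with the Markov boundary: the minimal set that
renders the target conditionally independent of everything else, and hence
the minimal maximally predictive feature set. That is why a classifier
restricted to the PC set should match one using all variables, a property
the test suite verifies on synthetic cohorts.

`max_k = 3` balances power against the sample sizes reachable at n in the
low hundreds; larger values exhaust the reliability heuristics and add
tests that can never reject.

### Classifier families and scoring

Seven families are adapted behind one interface (`fit_score()`): linear,
polynomial and RBF-kernel SVMs (`e1071`), random forest (`randomForest`),
lasso-penalized logistic regression (`glmnet`), plain logistic regression,
and logistic regression with classic forward-backward stepwise selection
on AIC (written in-package so its hill-climb contract — no improving
single add/remove at termination — is exactly testable, with a
ridge-stabilized fallback under separation). Each returns a continuous
case-likeness score; performance is the area under the ROC curve in its
Mann–Whitney midrank form, so ties count one half and any strictly
monotone rescaling of scores is irrelevant.

Margin and likelihood classifiers use inverse-prevalence class weights by
default: at 11 cases in 163 subjects an unweighted hinge loss happily
predicts "no case" everywhere. The choice is carried in every model spec
and logged. Hyperparameter grids (costs, kernel widths, degrees, lambda
path, mtry rules) follow conventional ranges and are configuration-exposed;
a `reduced = TRUE` screening variant of each grid is used by the package's
own simulation studies.

### Repeated nested cross-validation (RNNCV)

Error estimation uses N = 5 outer folds (each subject held out exactly
once per repeat, i.e. 80/20 splits), repeated 30 times by default over
fresh stratified fold assignments; an inner loop of N − 1 = 4 folds inside
each outer training set selects the hyperparameters. Stratification keeps
per-fold case counts within one of each other — with 11 positives,
unstratified splits regularly produce case-free test folds. All
preprocessing statistics and any feature selection are computed strictly
inside each outer training set.

**Aggregating held-out scores.** A repeat's held-out scores must become
one AUC. Pooling *raw* scores across folds looks natural but is measurably
pessimistic under the null: the five fold models have different score
scales and offsets, and those shifts anti-correlate with fold composition;
in 30-cohort null simulations the grand mean AUC sat around 0.44–0.47
rather than 0.50. The package therefore defaults to pooling *within-fold
normalized ranks* — each fold's scores are replaced by rank/(size+1)
before pooling — whose null expectation is exactly 0.5 by exchangeability,
while per-fold ordering (all the information AUC uses within a fold) is
preserved. Plain pooling and per-fold averaging remain available as
`auc_aggregation` options; per-fold averaging is unstable here because a
fold holds only 2–3 cases. Reported uncertainty is the across-repeat SD.

With very few cases (3 or fewer) the inner loop can become unscoreable —
no stratified inner split leaves both classes in every training portion —
in which case selection falls back to the first fittable grid entry with a
warning rather than aborting the outer estimate.

### Label-shuffling significance and protocol bias

`label_shuffle_test()` reruns the *entire* protocol on uniformly permuted
labels (400 permutations by default). The null distribution serves twice:
its mean diagnoses protocol bias (distance from 0.5 is the bias), and the
one-sided p-value for the observed AUC uses the add-one estimator
p = (1 + #{null ≥ observed})/(1 + B), which is never exactly zero.
Permutation reruns default to 5 outer repeats instead of 30: the null
*mean* is invariant to the repeat count, and the saving makes hundreds of
permutations tractable; a full-fidelity setting exists.

### Bootstrap stability

`bootstrap_stability()` draws 100 subject resamples (stratified by class so
no resample is case-free), reruns HITON-PC on each, and counts selections
per variable. Variables selected in strictly more than 20 of 100 resamples
form the stable set. Low frequency does not mean a variable is
uninformative: near-duplicate variables *split* their selection frequency
because the algorithm needs only one of an information-equivalent pair —
the test suite reproduces this on planted duplicate parents.

### Synthetic cohorts with known ground truth

`generate_cohort()` emulates the study conditions: 163 subjects, 105
variables (40% binary / 20% ordinal / 40% continuous by default), a binary
target at 7% prevalence driven through a logistic link by 5 planted parent
variables, 10 distractors built as noisy copies of parents (correlation
0.6), the rest independent noise; 5% MCAR missingness plus 3 noise columns
pushed above the 50% filter threshold. The intercept is solved by
root-finding on a Monte-Carlo draw of the linear predictor (tolerance well
under 0.002); default parent effects of 0.57 log-odds per standardized
unit put the Bayes-optimal AUC — computed by Monte-Carlo from the true
linear predictor, with a numeric-integration cross-check in the tests —
near 0.80, the headline regime of interest. Distractors are noisy copies
of parents rather than children of the target, because with a terminal
target that design makes the PC set equal the parent set exactly: the
cleanest possible ground truth for recovery tests.

What the generator does *not* emulate: real marginal distributions,
linkage structure among genetic variables, informative missingness, or
nonlinearity in the outcome model. Passing tests demonstrate correctness
of the machinery under the stated generative assumptions, not performance
guarantees on any particular real cohort.

## Problem sizes used by the test suite

The package's own validation runs are sized to finish in minutes on one
core, using the screening grids: null calibration uses 60 noise cohorts
across all seven families; the leakage sentinel 8 cohorts; graph recovery
20 cohorts at n = 5000 plus 30 per n ∈ {500, 2000, 8000};
Markov-boundary sufficiency 20 default-spec cohorts × 2 repeats. The
acceptance script reruns the protocol-bias check (50 label shuffles × 5
repeats) on a study-sized null cohort. Full-scale settings (30 repeats,
400 permutations, 100 bootstraps, full grids) are the function defaults a
user gets without asking.

## Known limitations

* The CI tests assume roughly monotone dependencies (Fisher-z) or coarse
  discretization (G²); purely non-monotone parent effects can be missed.
* At n ≈ 163 with 11 cases, HITON-PC has limited power: fold-wise selections
  are small and variable — which is precisely why the bootstrap stability
  layer exists.
* The permutation test reruns the protocol with reduced repeats by
  default; p-values for quantities other than the mean (e.g. extreme
  quantiles of the null) would need the full-fidelity setting.
* Exact reproduction of any specific historical analysis depends on
  unstated choices there (CI test, alpha, grids, class weighting); the
  package exposes all of them in configuration instead of hard-coding one
  guess.
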