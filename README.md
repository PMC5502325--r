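# mbrisk

Markov-boundary feature selection and repeated nested cross-validated risk
prediction for rare binary clinical outcomes.

## What problem this solves

Acute-phase cohort studies often face the same awkward geometry: a binary
outcome at ~7% prevalence, ~100+ mixed-type predictors, ~160 subjects, and
plenty of missing data. The motivating setting is predicting which injured
children will later meet a PTSD symptom threshold (an instrument score of
38 or greater) from variables collected during hospitalization. Two
questions matter: *how predictable is the outcome, honestly measured*, and
*which compact variable set carries all the non-redundant predictive
information* (the natural candidate set for causal interpretation and
intervention)?

`mbrisk` packages the full protocol:

* **Preprocessing** — drop variables missing >50% of entries, unsupervised
  k-nearest-neighbour imputation, 0–1 normalization (training-fold
  statistics only, no test-side clipping).
* **Causal feature selection** — semi-interleaved HITON-PC without
  symmetry correction over G²/Fisher-z conditional-independence tests.
  For a terminal target the selected parents-and-children (PC) set equals
  the Markov boundary: the minimal set X* with T ⊥ (V \ X*) | X*, hence
  the minimal maximally predictive feature set.
* **Error estimation** — repeated nested 5-fold cross-validation (inner
  4-fold loop for hyperparameter selection, 30 outer repeats) over seven
  classifier families: linear/polynomial/RBF SVM, random forest, lasso,
  logistic regression, stepwise logistic regression. Performance is AUC
  (Mann–Whitney form, ties = ½).
* **Significance** — label-shuffling permutation test of the whole
  protocol, with add-one p-values and a protocol-bias diagnostic (null
  mean AUC vs 0.5).
* **Stability** — HITON-PC selection frequency over 100 stratified
  bootstrap resamples; variables selected in >20 of 100 form the stable
  set.
* **Synthetic cohorts** — a generator with planted parents, correlated
  distractors, mixed variable kinds, calibrated prevalence and MCAR
  missingness, so every stage is testable against known ground truth.

## Worked example

```r
library(mbrisk)

spec <- synthetic_spec(seed = 4)     # 163 x 105, 7% prevalence, 5 parents
cohort <- generate_cohort(spec)
cohort$table
#> cohort_table: 163 subjects x 105 variables (1145 missing cells, 6.7%)
#> kinds: binary=36, categorical=20, continuous=49
cohort$truth
#> causal_truth: 5 parents, 10 distractors, bayes AUC 0.794

pp <- preprocess_cohort(cohort$table)
pp$report
#> preprocess_report: 3 variables dropped (missing > 0.5)
#>   839 cells imputed

pc <- run_hiton_pc(pp$table, cohort$target, alpha = 0.05, max_k = 3)
pc
#> pc_set (fisher_z, alpha=0.05, max_k=3): 5 selected of 13 admitted
#>   selected: V021, V047, V003, V045, V007
cohort$truth$parents
#> [1] "V003" "V073" "V026" "V086" "V009"

res <- run_rnncv(pp$table, cohort$target,
                 families = default_family_grids(c("random_forest", "lasso"),
                                                 reduced = TRUE),
                 n_repeats = 5, preprocess = FALSE, seed = 7)
summary(res)
#>          family  mean_auc     sd_auc
#> 1 random_forest 0.7309211 0.06311913
#> 2         lasso 0.7456340 0.06223387
```

Reading the output: the generated cohort's Bayes-optimal AUC (the best any
classifier could do, known because the generator's coefficients are known)
is 0.794; cross-validated random forest and lasso reach ~0.73–0.75, the
expected shortfall at n = 163 with 11 cases. At this sample size HITON-PC
recovers one true parent (`V003`) plus correlated stand-ins for others —
exactly the information-overlap behaviour the bootstrap stability stage
(`bootstrap_stability()`, `rank_stable()`) is there to quantify. The
one-command driver `run_full_analysis()` chains every stage and emits the
classifier-by-selection performance table with permutation stars, the
stability frequency table, and a run manifest.

Real data enters through `read_cohort()` (tab-delimited or CSV with a
header; optional YAML sidecar naming the outcome column, its cutoff —
default 38 — and variable-kind overrides).

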