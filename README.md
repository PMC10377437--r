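# pvte — thromboembolic risk modelling for hydroxyurea-treated polycythemia vera cohorts

Patients with polycythemia vera (PV) carry a high risk of thromboembolic
events (TE), and hydroxyurea (HU) — the standard first-line cytoreductive
therapy — does not remove that risk. `pvte` is an R package for
epidemiologists and biostatisticians studying TE risk in HU-treated PV
cohorts abstracted from electronic health records. It implements the full
analysis pipeline on patient-level tables (demographics, TE history,
summarized laboratory and observation medians, treatment dates, TE event
times):

* **Cohort model and eligibility** — CSV I/O with enforced record invariants
  and the cohort-selection rules (age, prescription counts, diagnosis
  exclusions, treatment-duration / follow-up / lab-presence requirements).
* **Synthetic cohorts** — a generator with planted hazard structure
  (log-normal lab marginals, an NEP–LYP copula, TE-history / anticoagulant /
  age effects and threshold-quadrant interactions), so the whole pipeline is
  testable without proprietary data.
* **Period-aligned incidence** — pre-index / post-index / switch periods,
  annualized incidence rates per 100 patient-years, and greedy 1:1
  propensity-score matching with caliper and balance diagnostics.
* **Survival utilities** — Kaplan–Meier curves and the k-group log-rank
  test.
* **Risk model** — a random survival forest with log-rank splitting on the
  windowed time-to-TE outcome (6–18 months post-index), out-of-bag risk
  scores, a windowed ROC-AUC, and drop-column variable importance.
* **Synergy screen** — for a variable pair, the score
  `(p1 × p2) / p_joint`: the product of the two single-variable median-split
  log-rank p-values (what independence would predict) over the four-quadrant
  model's p-value (what the pair achieves). Scores ≫ 1 flag synergistic
  pairs.
* **Risk landscape and decision trees** — a log-rank p-value matrix over a
  grid of threshold pairs, extraction of the most significant cell, two-level
  high/low-risk decision trees, and fixed-threshold validation on independent
  cohorts.

## Worked example

```r
library(pvte)

# 1. simulate a development cohort and apply the risk-model eligibility rules
cohort <- generate_cohort(generator_config(n_patients = 2000, seed = 42))
eligible <- apply_eligibility(cohort, rsf_eligibility_criteria())
print(eligible)
#> <pv_cohort 'synthetic-ehr': 1529 patients, 3959 TE events>

# 2. fit the random survival forest and evaluate it out of bag
fit <- fit_rsf(eligible, rsf_config(n_trees = 200, seed = 42))
round(windowed_auc(fit), 3)
#> [1] 0.821

# 3. screen the headline variable pair in patients without TE history
pair_interaction(eligible, "NEP", "RDW", stratum = "without_te")[
  , c("expected_p", "observed_p", "score")]
#>     expected_p   observed_p    score
#> 1 1.782801e-12 6.978222e-17 25548.08

# 4. search the two-variable risk landscape and extract the optimal thresholds
landscape <- pvalue_matrix(filter_stratum(eligible, "without_te"), "NEP", "RDW")
optimal_thresholds(landscape)
#> risk group: NEP >= 72.54 & RDW < 14.12 (p = 2.11e-93, n = 88)

# 5. freeze thresholds into a decision tree; validate on an independent cohort
tree <- build_decision_tree(var1 = "NEP", threshold1 = 72.05, direction1 = ">=",
                            var2 = "RDW", threshold2 = 14.3, direction2 = "<")
validation <- generate_validation_cohort(n_patients = 300, seed = 7)
validate_fixed_thresholds(tree, validation)
#> fixed-threshold validation (without_te): high 17 vs low 170,
#> log-rank: chi2 = 68.22 on 1 df, p = 1.46e-16 (2 groups)
```

Reading the numbers: the out-of-bag AUC of 0.821 is the probability that a
randomly chosen patient who thrombosed in the 6–18-month window outranks one
who did not; the synergy score of ~2.5 × 10⁴ says the NEP×RDW quadrant split
is vastly more significant than the product of the two median splits; the
landscape argmin lands within one grid step of the planted thresholds
(NEP ≥ 72.05, RDW < 14.3); and the frozen tree separates thrombosis-free
survival decisively (p = 1.5 × 10⁻¹⁶) in an independent cohort generated with
the same planted quadrant effects.

The methods vignette (`vignettes/te-risk-modelling.Rmd`) documents the model,
the generator's design and calibration, numerical conventions and known
limitations.

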