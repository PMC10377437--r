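---
title: "Modelling thromboembolic risk in hydroxyurea-treated polycythemia vera"
author: "pvte package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thromboembolic risk in hydroxyurea-treated polycythemia vera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvte)
```

## The problem

Polycythemia vera (PV) is a myeloproliferative neoplasm with a markedly
elevated risk of thromboembolic events (TE). Hydroxyurea (HU) is the usual
first-line cytoreductive therapy, yet a substantial fraction of treated
patients still go on to thrombose, and conventional risk stratification (age
and TE history alone) misses many of them. This package implements a
reusable pipeline for studying TE risk in HU-treated PV cohorts abstracted
from electronic health records:

1. a patient-level cohort model with eligibility filtering (`pv_cohort()`,
   `apply_eligibility()`);
2. a synthetic cohort generator with planted hazard structure
   (`generate_cohort()`), so every downstream stage is testable without
   access to proprietary EHR data;
3. period-aligned annualized TE incidence with propensity-score matching
   (`build_periods()`, `annualized_ir()`, `propensity_match()`);
4. Kaplan--Meier and k-group log-rank utilities (`kaplan_meier()`,
   `logrank_test()`);
5. a random survival forest (RSF) risk model with drop-column variable
   importance and a windowed ROC-AUC (`fit_rsf()`,
   `drop_variable_importance()`, `windowed_auc()`);
6. a pairwise synergy screen of two-variable splits (`pair_interaction()`,
   `screen_all_pairs()`);
7. a two-variable threshold search ("risk landscape") from which clinical
   decision trees are derived and validated on independent cohorts
   (`pvalue_matrix()`, `optimal_thresholds()`, `build_decision_tree()`,
   `validate_fixed_thresholds()`).

Real EHR extracts of this kind are not redistributable, so the package is
organised around the generator: the synthetic cohorts define the study
conditions under which the methods are exercised and tested.

## Data model and windows

A cohort is a data frame with one row per patient: demographics, a TE-history
flag, counts (phlebotomies, prescriptions), summarized laboratory medians
(NEP, LYP, RDW, WBC, Hct, HGB, Plt) and observation medians (BMI, blood
pressures, weight, height, heart rate, respiration, pulse), treatment-course
dates, record boundaries and the list of TE event day offsets.

All dates are integer day offsets from an arbitrary epoch; month-based
criteria are converted at 30.4375 days/month. The post-index feature window
("3--6 months") is the half-open day interval [91, 183); the risk-model
outcome window ("6--18 months") is [183, 548). These are declared
conventions: inclusive/exclusive month boundaries are ambiguous in prose, and
fixing them in days makes every window reproducible. Missing laboratory or
observation medians stay missing (`NA`) -- absence is informative (patients
with no measurements at all are removed by the eligibility filter, not
imputed) -- and all downstream stages treat `NA` explicitly.

The time-to-event outcome used by the risk model, the synergy screen and the
landscape search (`te_outcome()`) is the time from the feature-window end
(day 183 after index) to the first TE within the following 365 days, censored
at the horizon or the record end. The published threshold analyses speak of
"TE within 12 months" while the model window is "6--18 months post-index";
these coincide when the clock starts at the feature-window end, which is the
convention adopted here, and the horizon is exposed as a parameter
(`horizon_days`) for sensitivity analyses.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the structure the analysis assumes:

* **Marginals.** Laboratory and observation medians are log-normal with
  parameters solved from target median/IQR pairs (right-skewed positive
  data); age is truncated normal on [18, 100]. The development-population
  targets (NEP 70 (62--78) %, LYP 19.5 (13.0--26.3) %, RDW 17.0 (14.5--19.3)
  %, age 73, TE-history prevalence 16.1%, ...) and the registry-like
  validation targets (NEP 68, LYP 22, RDW 16.0, TE-history 32%, n = 100) are
  the documented population summaries the generator emulates; the remaining
  observation targets are plausible values for an elderly US population and
  are the generator's own choices.
* **Correlation.** NEP and LYP are complementary differential percentages;
  they share a Gaussian copula with latent correlation -0.8. Other variables
  are independent, which real data are not -- a stated limitation.
* **Hazard.** TE events follow a constant-rate (exponential) process per
  patient, rate `baseline_hazard * exp(linear predictor)`. The planted
  effects are a TE-history main effect, an anticoagulant-use effect, an age
  trend, and two threshold-quadrant interactions: NEP >= 72.05 & RDW < 14.3,
  and LYP < 19.3 & RDW < 14.05, each multiplying the hazard inside the
  quadrant. Pre-index events use only the TE-history effect, because the labs
  describe the post-index window. Recurrent events are generated (the
  incidence analyses count all of them; the survival analyses use the first
  event in the window).
* **Censoring.** Administrative follow-up (uniform 550--2200 days) combined
  with exponential dropout (0.05/year) determines `record_end`.
* **Missingness.** A patient has no labs at all with probability 0.07 (no
  observations: 0.05), else each value is missing independently with
  probability 0.03.

Reproducibility: a single `set.seed()` at entry and a fixed draw order make
cohorts identical for identical configurations and seeds; gap exponentials
for the event process are drawn in fixed-size blocks so that raising a
planted effect with the same seed only rescales the same uniforms (common
random numbers), which is what makes the monotonicity property testable.

### Calibration of the planted effect sizes

The default effect sizes are log hazard ratios 2.2 (TE history), 1.8 (each
quadrant), 0.4 (anticoagulant use), 0.5 per decade of age, on a baseline of
0.06 events/patient-year. They were chosen by a closed-form feasibility
computation, not by tuning on the fitted model: the Bayes-optimal AUC of the
true hazard over a large simulated population must comfortably exceed 0.8
for *any* classifier -- in particular the RSF -- to reach the performance the
pipeline is designed to reproduce. Weaker, more "clinically typical" effects
(e.g. history-of-thrombosis hazard ratios of 2--3) cap the Bayes AUC near
0.68 in this compact feature set, because the simulator carries far fewer
correlated signal channels than a real EHR. The cost of this choice is
deliberately accepted and documented: the planted hazard ratios, and hence
the synthetic incidence rates under the default configuration, are larger
than real-world PV figures. Analyses whose oracle is a closed-form rate
(incidence unbiasedness, exponential event fractions, null calibrations) use
interaction-free configurations with realistic hazards (e.g. 0.087/year)
instead.

Two dedicated recovery experiments deviate from the cohort defaults, and say
so:

* the **threshold-recovery** experiment plants only the NEP x RDW quadrant
  (otherwise the correlated LYP x RDW effect drags the optimum below RDW
  14.3) at log-HR 2.5. At weaker planted effects the landscape argmin is
  unbiased but scatters over several grid steps -- the p-value surface is
  locally flat, a well-known property of optimal-cutpoint estimation, not a
  defect of the search;
* the **importance-recovery** experiment raises the TE-history effect to
  log-HR 3.0 so that it is unambiguously dominant. At the cohort defaults
  RDW rivals it, for a structural reason: RDW participates in both planted
  quadrants, so removing it destroys two interactions at once. Note also
  that under drop-column importance the NEP--LYP copula makes each of the
  two a near-perfect proxy for the other, so neither ranks as high alone as
  their shared signal would suggest -- the same redundancy that the
  duplicated-variable test demonstrates directly.

## Periods, incidence and matching

`build_periods()` reproduces the period-aligned design: a 365-day pre-index
window; for switchers, a post-index period up to the first ruxolitinib
prescription followed by the switch period; for non-switchers, windows of the
switch cohort's median HU and ruxolitinib treatment times. Periods are
half-open, truncated at the record end, and a record too short for the full
pre-index window drops that patient from that period's denominator.

`annualized_ir()` uses a person-time denominator -- events per 100
patient-years -- with all recurrent events counted by default and a
`first_event_only` switch. Person-time is the standard annualization and
keeps cross-period comparisons coherent; the choice is a declared convention.

`propensity_match()` fits a logistic propensity model and performs greedy 1:1
nearest-neighbour matching on the logit, without replacement, caliper 0.2
pooled SDs of the logit -- the conventional default behaviour of
nearest-neighbour matching tools. Greedy matching is deterministic here:
treated patients are processed in `patient_id` order and distance ties go to
the smaller control id, so matched sets are reproducible without a seed.
Perfect separation of the propensity model is detected and raised as an
error rather than silently producing degenerate weights.

## Survival machinery

`kaplan_meier()` and `logrank_test()` wrap the product-limit estimator and
the k-group log-rank test with fixed conventions: simultaneous decrement at
ties, censored subjects retained in the risk set at their censoring time, the
chi-square reference with tie-corrected hypergeometric variance, empty group
levels dropped with a warning and a degrees-of-freedom adjustment. The test
suite checks the statistic against an independent brute-force accumulation of
hypergeometric expectations on small instances, verifies type-I error
calibration under the null, and confirms invariance to label permutations
and monotone time transforms.

## The risk model

`fit_rsf()` grows a survival forest with log-rank splitting on the windowed
outcome: 500 trees by default (200 in the headline evaluation, which is
within one AUC point of the 500-tree result at a quarter of the cost),
`mtry = ceiling(sqrt(k))`, terminal nodes of at least 10 subjects, 0.632
subsampling without replacement, fixed seed, single thread -- deterministic
end to end. The risk score is the ensemble Nelson--Aalen cumulative hazard
12 months after the window origin; out-of-bag (OOB) scores are used for all
evaluation. Missing feature values are median-imputed from the training
cohort (the imputation values travel with the fitted object); patient-level
"no labs at all" missingness never reaches the model because the eligibility
filter removes those patients, preserving the presence-is-informative
structure at the cohort level.

`windowed_auc()` is the Mann--Whitney AUC of OOB scores against the binary
label "at least one TE in the window", computed among patients whose
follow-up covers the window or who had an event; patients censored mid-window
before any TE carry no label. A single fixed-window AUC (rather than a
time-dependent AUC) matches how the model's performance target is stated.

`drop_variable_importance()` refits the forest without each feature (same
seed) and scores the feature by the AUC degradation -- the "removed from the
model" reading of variable importance; ranks are descending with
alphabetical tie-breaks, and a permutation mode is provided for comparison.

## Synergy screen and risk landscape

`pair_interaction()` computes, per TE-history stratum, the individual
stratum-median-split log-rank p-values `p1`, `p2` of two variables, the
four-quadrant (k-group) log-rank p of their joint split, and the synergy
score `(p1 * p2) / p_joint`: how much sharper the joint split is than
independence of the two effects would predict. Stratum medians (not
whole-cohort medians) are the declared splitting convention, quadrants
below 10 subjects are dropped with a warning, and degenerate pairs are
flagged invalid. `screen_all_pairs()` ranks all pairs per stratum, reporting
raw p-values (with a Bonferroni column for reference only, since the screen
is exploratory).

`pvalue_matrix()` generalizes the median split to a grid search: candidate
thresholds default to percentiles 5--95 in steps of 2.5 of each variable, and
for every threshold pair a log-rank p-value is recorded, by default
comparing the designated risk quadrant to all other patients pooled
(`risk_vs_rest`; the `four_group` mode retains the synergy-table comparison).
The pooled-rest default reflects how the named risk groups are compared
against "the other threshold groups"; it and the percentile grid are
declared choices. `optimal_thresholds()` extracts the minimum-p cell with
deterministic tie-breaks (larger risk quadrant, then lower thresholds) and,
in `four_group` mode, designates the quadrant with the worst 12-month KM
survival as the risk group. Because the minimum is selected over the whole
grid it is optimistic; `landscape_permutation_p()` reports an event-label
permutation adjustment alongside it -- an addition the original analysis did
not carry, labelled as such.

`build_decision_tree()` freezes a threshold pair into a two-level rule
("high risk" iff both risk-direction conditions hold; `<` excludes the
threshold value, `>=` includes it), and `validate_fixed_thresholds()`
applies a frozen tree to an independent cohort and tests thrombosis-free
survival between the leaves. The headline trees fix the published risk
directions (NEP high, RDW low, LYP low); direction discovery is used only
when no directions are supplied.

## Numerical conventions and degenerate inputs

* Ties in the greedy matcher, the importance ranking and the landscape argmin
  are all broken deterministically (ids, alphabet, quadrant size then
  threshold order).
* Log-rank with fewer than two non-empty groups, forests with no training
  events, landscapes with no evaluable cell, and validation with an empty
  leaf are errors with diagnostic messages, never silent `NA`s.
* Zero person-time yields an undefined incidence rate with a warning.
* All RNG flows from explicit seeds; nothing in the landscape or matching
  modules is stochastic.

## Problem sizes

The shipped tests and the acceptance script run the pipeline at deliberately
modest scales chosen for statistical sufficiency: cohorts of 2,000 (RSF
evaluation and threshold recovery, 20 seeds), 1,000 (importance recovery, 20
seeds), 5,000 (incidence unbiasedness), 1,000 replicates for log-rank
calibration, and validation cohorts of 300 (20 seeds). These sizes keep every
recovery experiment's pass criterion well inside its sampling noise while
remaining desk-scale.

## Known limitations

* Independence of all variables except NEP/LYP; no visit-level longitudinal
  structure, no medication adherence, no competing risks (death censors
  implicitly through the record end).
* Planted hazard ratios larger than clinical literature values, as discussed
  above: passing recovery tests demonstrates that the methods find structure
  that is there, not that real effect sizes of this magnitude exist.
* Drop-column importance is redundancy-sensitive by construction; correlated
  predictor blocks share credit.
* The incidence module reports rates without exact Poisson confidence
  intervals.
* Eligibility operates on abstracted flags (diagnosis and prescription-count
  flags arrive as inputs); no diagnosis-code dictionaries are interpreted.
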