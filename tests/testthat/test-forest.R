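test_that("the windowed outcome encodes event, censoring and label rules", {
  co <- toy_cohort(
    # event inside the 6-18-month window
    toy_patient("W1", record_end = 2000, te_times = list(c(1400))),
    # event before the window origin only: censored at the horizon
    toy_patient("W2", record_end = 2000, te_times = list(c(1100))),
    # record ends inside the window without event: label excluded (NA)
    toy_patient("W3", record_end = 1300),
    # record ends before the window origin: excluded entirely
    toy_patient("W4", record_end = 1100, hu_last = 1090),
    # event exactly at the window end is outside the half-open window
    toy_patient("W5", record_end = 2000, te_times = list(c(1548)))
  )
  out <- te_outcome(co)
  expect_setequal(out$patient_id, c("W1", "W2", "W3", "W5"))
  w <- function(id, col) out[out$patient_id == id, col]
  expect_equal(w("W1", "time"), 1400 - 1183)
  expect_equal(w("W1", "event"), 1L)
  expect_equal(w("W1", "label"), 1L)
  expect_equal(w("W2", "time"), 365)
  expect_equal(w("W2", "event"), 0L)
  expect_equal(w("W2", "label"), 0L)
  expect_equal(w("W3", "time"), 1300 - 1183)
  expect_true(is.na(w("W3", "label")))
  expect_equal(w("W5", "event"), 0L)
  expect_equal(w("W5", "label"), 0L)
})

test_that("fitting is deterministic and scores repeat for identical patients", {
  co <- apply_eligibility(generate_cohort(generator_config(600, seed = 301)),
                          rsf_eligibility_criteria())
  cfg <- rsf_config(n_trees = 60, seed = 9)
  f1 <- fit_rsf(co, cfg)
  f2 <- fit_rsf(co, cfg)
  expect_identical(predict_risk(f1), predict_risk(f2))
  # clone one patient: identical feature vectors get identical scores
  clone <- co[c(1, 1), ]
  sc <- predict_risk(f1, clone)
  expect_equal(sc[1], sc[2])
})

test_that("a pure-noise feature gives a chance-level OOB AUC", {
  aucs <- vapply(1:5, function(s) {
    co <- generate_cohort(flat_config(700, seed = 400 + s, hazard = 0.25,
                                      admin = c(1500, 1500)))
    f <- fit_rsf(co, rsf_config(n_trees = 80, seed = s, features = "WBC"))
    windowed_auc(f)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("with one strong planted effect the forest approaches the best single split", {
  # plant a main effect carried by NEP alone (the paired condition is vacuous)
  ia <- data.frame(var1 = "NEP", threshold1 = 72.05, direction1 = ">=",
                   var2 = "RDW", threshold2 = 1e6, direction2 = "<",
                   log_hr = 2)
  cfg <- generator_config(n_patients = 1200, seed = 47,
                          effects = c(te_history = 0, anticoag = 0,
                                      age_per_decade = 0),
                          interactions = ia,
                          lab_block_missing_rate = 0, item_missing_rate = 0)
  co <- generate_cohort(cfg)
  f <- fit_rsf(co, rsf_config(n_trees = 150, seed = 3, features = "NEP"))
  auc_f <- windowed_auc(f)
  out <- f$outcome
  nep <- co$NEP[match(out$patient_id, co$patient_id)]
  auc_best <- best_single_split_auc(nep, out$label)
  expect_gt(auc_f, auc_best - 0.05)
})

test_that("risk scores move with a patient toward the planted quadrant", {
  co <- apply_eligibility(
    generate_cohort(generator_config(1200, seed = 13)),
    rsf_eligibility_criteria())
  f <- fit_rsf(co, rsf_config(n_trees = 120, seed = 5))
  base <- co[rep(1, 100), ]
  base$RDW <- 13.5
  base$te_history <- FALSE
  low <- base
  low$NEP <- 65
  high <- base
  high$NEP <- 80
  # vary an irrelevant covariate across the 100 copies so scores differ
  base_ages <- seq(60, 85, length.out = 100)
  low$age_at_index <- base_ages
  high$age_at_index <- base_ages
  expect_gt(mean(predict_risk(f, high)), mean(predict_risk(f, low)))
})

test_that("single-split tree structure yields exactly two distinct scores", {
  co <- apply_eligibility(generate_cohort(generator_config(500, seed = 99)),
                          rsf_eligibility_criteria())
  f <- fit_rsf(co, rsf_config(n_trees = 1, seed = 1, max_depth = 1,
                              features = c("NEP", "RDW")))
  sc <- predict_risk(f, co)
  expect_lte(length(unique(sc)), 2L)
})

test_that("Mann-Whitney AUC has its closed-form edge values", {
  expect_equal(mann_whitney_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(mann_whitney_auc(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(mann_whitney_auc(10:1, c(rep(0, 5), rep(1, 5))), 0)
  expect_true(is.na(mann_whitney_auc(1:4, rep(1, 4))))
})

test_that("drop-column importance ranks the dominant planted factor first", {
  co <- apply_eligibility(
    generate_cohort(generator_config(1000, seed = 71)),
    rsf_eligibility_criteria())
  imp <- drop_variable_importance(co, rsf_config(n_trees = 60, seed = 2))
  expect_equal(sort(imp$rank), seq_along(imp$rank))
  expect_equal(imp$variable[imp$rank == 1], "te_history")
  expect_true(all(diff(imp$score) <= 0))
})

test_that("duplicating a variable dilutes its individual importance", {
  cfg <- generator_config(n_patients = 900, seed = 23,
                          lab_block_missing_rate = 0, item_missing_rate = 0)
  co <- generate_cohort(cfg)
  feats <- c("te_history", "NEP", "RDW", "WBC")
  imp1 <- drop_variable_importance(
    co, rsf_config(n_trees = 80, seed = 4, features = feats))
  co2 <- co
  co2$te_history2 <- co$te_history
  imp2 <- drop_variable_importance(
    co2, rsf_config(n_trees = 80, seed = 4,
                    features = c(feats, "te_history2")))
  s1 <- imp1$score[imp1$variable == "te_history"]
  s2 <- imp2$score[imp2$variable == "te_history"]
  expect_lt(s2, s1)
})

test_that("permutation importance is available and flags the same signal", {
  co <- apply_eligibility(
    generate_cohort(generator_config(800, seed = 81)),
    rsf_eligibility_criteria())
  imp <- drop_variable_importance(co, rsf_config(n_trees = 80, seed = 6),
                                  method = "permutation")
  expect_equal(imp$variable[imp$rank == 1], "te_history")
})

test_that("degenerate fits are rejected with clear errors", {
  co <- toy_cohort(toy_patient("X1", record_end = 2000),
                   toy_patient("X2", record_end = 2000))
  expect_error(fit_rsf(co, rsf_config(n_trees = 5)), "no TE events")
  expect_error(rsf_config(mtry = 50), "mtry")
  expect_error(predict_risk(list()), "pv_rsf")
})
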