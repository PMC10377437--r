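# Hand-built toy cohorts for unit tests (all fields explicit, no randomness).

toy_patient <- function(patient_id = "P1",
                        age_at_index = 70, sex = "F", race = "White",
                        region = "South", te_history = FALSE,
                        n_phlebotomy = 1, anticoag_antiplatelet = FALSE,
                        smoking = FALSE, alcohol = FALSE,
                        NEP = 70, LYP = 20, RDW = 16, WBC = 8, Hct = 43,
                        HGB = 140, Plt = 280,
                        BMI = 28, DBP = 76, SBP = 128, weight = 80,
                        height = 170, HRT = 76, RSP = 16, PLS = 76,
                        index_date = 1000, hu_first = 1000, hu_last = 1600,
                        rux_first = NA_real_, rux_last = NA_real_,
                        record_start = 0, record_end = 2000,
                        te_times = list(numeric(0)),
                        has_mf_et = FALSE, has_other_cytoreductive = FALSE,
                        n_hu_prescriptions = 5, n_rux_prescriptions = 0) {
  df <- data.frame(patient_id = patient_id, age_at_index = age_at_index,
                   sex = sex, race = race, region = region,
                   te_history = te_history, n_phlebotomy = n_phlebotomy,
                   anticoag_antiplatelet = anticoag_antiplatelet,
                   smoking = smoking, alcohol = alcohol,
                   NEP = NEP, LYP = LYP, RDW = RDW, WBC = WBC, Hct = Hct,
                   HGB = HGB, Plt = Plt, BMI = BMI, DBP = DBP, SBP = SBP,
                   weight = weight, height = height, HRT = HRT, RSP = RSP,
                   PLS = PLS, index_date = index_date, hu_first = hu_first,
                   hu_last = hu_last, rux_first = rux_first,
                   rux_last = rux_last, record_start = record_start,
                   record_end = record_end,
                   has_mf_et = has_mf_et,
                   has_other_cytoreductive = has_other_cytoreductive,
                   n_hu_prescriptions = n_hu_prescriptions,
                   n_rux_prescriptions = n_rux_prescriptions,
                   stringsAsFactors = FALSE)
  df$te_times <- te_times
  df
}

toy_cohort <- function(..., label = "toy") {
  pv_cohort(do.call(rbind, list(...)), label = label)
}

# interaction-free generator configuration with a single constant hazard,
# used wherever a closed-form Poisson/exponential expectation is the oracle
flat_config <- function(n, seed, hazard = 0.087, admin = c(730, 730),
                        dropout = 0) {
  generator_config(
    n_patients = n, seed = seed, baseline_hazard = hazard,
    effects = c(te_history = 0, anticoag = 0, age_per_decade = 0),
    interactions = default_interactions(log_hr = 0),
    dropout_rate = dropout,
    lab_block_missing_rate = 0, obs_block_missing_rate = 0,
    item_missing_rate = 0,
    admin_followup_range = admin)
}

# configuration with only the NEP x RDW quadrant effect planted, used by the
# threshold-recovery experiments
nep_rdw_only_config <- function(n, seed, log_hr = 2.5) {
  ia <- default_interactions(log_hr = log_hr)[1, ]
  generator_config(n_patients = n, seed = seed,
                   effects = c(te_history = 0, anticoag = 0,
                               age_per_decade = 0),
                   interactions = ia)
}
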