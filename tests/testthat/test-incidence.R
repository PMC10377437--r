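test_that("period construction follows the index/switch arithmetic", {
  sw <- toy_cohort(toy_patient("S1", rux_first = 1400, rux_last = 1900,
                               hu_last = 1400, record_end = 2000))
  per <- build_periods(sw[1, ], median_hu_time = 400, median_rux_time = 500)
  expect_equal(per$period, c("pre_index", "post_index", "switch"))
  expect_equal(per$start, c(635, 1000, 1400))
  expect_equal(per$end, c(1000, 1400, 1900))

  ns <- toy_cohort(toy_patient("N1", record_end = 2000))
  per2 <- build_periods(ns[1, ], median_hu_time = 400, median_rux_time = 500)
  expect_equal(per2$period, c("pre_index", "post_index", "no_switch"))
  expect_equal(per2$start, c(635, 1000, 1400))
  expect_equal(per2$end, c(1000, 1400, 1900))
})

test_that("periods are truncated at the record end and short records flagged", {
  ns <- toy_cohort(toy_patient("T1", record_end = 1200))
  per <- build_periods(ns[1, ], 400, 500)
  expect_equal(per$period, c("pre_index", "post_index"))
  expect_equal(per$end, c(1000, 1200))

  short <- toy_cohort(toy_patient("T2", record_start = 800))
  per2 <- build_periods(short[1, ], 400, 500)
  expect_false("pre_index" %in% per2$period)
  expect_equal(attr(per2, "dropped"), "pre_index")
})

test_that("period person-time never exceeds the record length", {
  co <- generate_cohort(generator_config(n_patients = 200, seed = 8,
                                         switch_fraction = 0.3))
  per <- cohort_periods(co)
  tot <- tapply(per$end - per$start, per$patient_id, sum)
  rec_len <- (co$record_end - co$record_start)[match(names(tot), co$patient_id)]
  expect_true(all(tot <= rec_len + 1e-9))
  expect_true(all(per$end > per$start))
})

test_that("the incidence rate is events per 100 person-years by definition", {
  co <- toy_cohort(
    toy_patient("I1", record_start = -9000, record_end = 11000,
                te_times = list(c(100, 5000))),
    toy_patient("I2", record_start = -9000, record_end = 11000)
  )
  # post_index for non-switchers: [1000, 1000 + median_hu_time)
  per <- cohort_periods(co, median_hu_time = 9131.25, median_rux_time = 10)
  ir <- annualized_ir(co, per, "post_index")
  expect_equal(ir$person_years, 50)
  expect_equal(ir$events, 1L + 0L)  # only the in-period event counts
  expect_equal(ir$ir_per_100, 100 * 1 / 50)

  ir0 <- annualized_ir(co, per, "no_switch")
  expect_equal(ir0$events, 0)
  expect_equal(ir0$ir_per_100, 0)
})

test_that("recurrent events can be restricted to the first per period", {
  co <- toy_cohort(toy_patient("R1", record_end = 3000,
                               te_times = list(c(1100, 1200, 1300))))
  per <- cohort_periods(co, median_hu_time = 1000, median_rux_time = 500)
  expect_equal(annualized_ir(co, per, "post_index")$events, 3)
  expect_equal(annualized_ir(co, per, "post_index",
                             first_event_only = TRUE)$events, 1)
})

test_that("zero person-time yields an undefined rate with a warning", {
  co <- toy_cohort(toy_patient("Z1"))
  per <- data.frame(patient_id = "Z1", period = "pre_index",
                    start = 500, end = 500)
  expect_warning(ir <- annualized_ir(co, per, "pre_index"), "undefined")
  expect_true(is.na(ir$ir_per_100))
})

test_that("the IR estimator is unbiased for a planted constant hazard", {
  h <- 0.087
  co <- generate_cohort(flat_config(5000, seed = 55, hazard = h,
                                    admin = c(1500, 1500)))
  per <- cohort_periods(co, median_hu_time = 400, median_rux_time = 500)
  ir <- annualized_ir(co, per, "pre_index")
  se <- 100 * sqrt(ir$events) / ir$person_years
  expect_lt(abs(ir$ir_per_100 - 100 * h), 3 * se)
})

test_that("greedy matching agrees with an independent oracle and the caliper", {
  set.seed(6)
  for (rep in 1:20) {
    nt <- sample(2:6, 1); nc <- sample(3:9, 1)
    st <- runif(nt); sc <- runif(nc)
    idt <- sprintf("T%02d", sample(99, nt))
    idc <- sprintf("C%02d", sample(99, nc))
    cal <- sample(c(Inf, 0.2), 1)
    got <- pvte:::greedy_nn_match(st, sc, idt, idc, caliper = cal)
    want <- greedy_oracle(st, sc, idt, idc, caliper = cal)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$treated_id, want$treated_id)
      expect_equal(got$control_id, want$control_id)
      expect_equal(got$distance, want$distance, tolerance = 1e-12)
    }
    expect_true(all(got$distance <= cal))
    expect_false(anyDuplicated(got$control_id) > 0)
  }
})

test_that("propensity matching balances covariates and handles edge cases", {
  cfg <- generator_config(n_patients = 400, seed = 19, switch_fraction = 0.35)
  co <- generate_cohort(cfg)
  treated <- co[!is.na(co$rux_first), ]
  controls <- co[is.na(co$rux_first), ]
  m <- propensity_match(treated, controls,
                        c("age_at_index", "sex", "race", "region"))
  expect_lte(nrow(m$pairs), nrow(treated))
  expect_false(anyDuplicated(m$pairs$control_id) > 0)
  # matched controls drawn from the same covariate distribution: balance must
  # not blow up relative to the pre-match comparison
  worsened <- m$balance$smd_post > pmax(m$balance$smd_pre, 0.1) + 0.1
  expect_false(any(worsened, na.rm = TRUE))

  empty <- propensity_match(treated[0, ], controls, c("age_at_index"))
  expect_equal(nrow(empty$pairs), 0L)

  # identical covariates on both sides: perfect post-match balance
  t2 <- treated; t2$age_at_index <- 70
  c2 <- controls; c2$age_at_index <- 70
  m2 <- propensity_match(t2, c2, "age_at_index")
  expect_true(all(m2$balance$smd_post == 0))
})

test_that("a perfectly separating covariate raises a separation error", {
  co <- generate_cohort(generator_config(n_patients = 100, seed = 2,
                                         switch_fraction = 0.4))
  treated <- co[!is.na(co$rux_first), ]
  controls <- co[is.na(co$rux_first), ]
  treated$sep <- 10
  controls$sep <- -10
  expect_error(propensity_match(treated, controls, "sep"), "separat")
})
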