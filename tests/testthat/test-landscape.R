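test_that("a single-cell landscape reduces to one log-rank dichotomy", {
  co <- generate_cohort(generator_config(n_patients = 500, seed = 20))
  ls <- pvalue_matrix(co, "NEP", "RDW", grid1 = 70, grid2 = 15,
                      mode = "risk_vs_rest")
  expect_equal(dim(ls$p), c(1L, 1L))
  out <- te_outcome(co)
  idx <- match(out$patient_id, co$patient_id)
  v1 <- co$NEP[idx]; v2 <- co$RDW[idx]
  ok <- !is.na(v1) & !is.na(v2)
  risk <- v1[ok] >= 70 & v2[ok] < 15
  lr <- logrank_test(out$time[ok], out$event[ok], risk)
  expect_equal(ls$p[1, 1], lr$p, tolerance = 1e-12)
})

test_that("landscapes are deterministic and exportable in long format", {
  co <- generate_cohort(generator_config(n_patients = 500, seed = 26))
  sub <- filter_stratum(co, "without_te")
  g1 <- c(65, 70, 75); g2 <- c(14, 15, 16)
  a <- pvalue_matrix(sub, "NEP", "RDW", g1, g2)
  b <- pvalue_matrix(sub, "NEP", "RDW", g1, g2)
  expect_identical(a$p, b$p)
  tab <- landscape_table(a)
  expect_equal(nrow(tab), 9L)
  expect_equal(tab$p[tab$t1 == 70 & tab$t2 == 15], a$p[2, 2])
})

test_that("cells with undersized groups are absent and out-of-range grids warn", {
  co <- generate_cohort(generator_config(n_patients = 200, seed = 29))
  expect_warning(
    ls <- pvalue_matrix(co, "NEP", "RDW", grid1 = c(1, 70),
                        grid2 = c(15, 10000)),
    "range")
  expect_true(is.na(ls$p[1, 2]))  # nobody satisfies NEP >= 1 & RDW < 10000? risk = all
  # risk group of everyone leaves no "rest": absent as well
  expect_true(all(is.na(ls$p[, 2]) | ls$n_risk[, 2] < nrow(co)))
})

test_that("optimal thresholds pick the minimum cell with the stated tie rules", {
  skel <- structure(list(
    var1 = "NEP", var2 = "RDW",
    grid1 = c(60, 70), grid2 = c(14, 15),
    p = matrix(c(0.5, 0.01, 0.01, 0.9), 2, 2),
    n_risk = matrix(c(50L, 10L, 40L, 5L), 2, 2),
    mode = "risk_vs_rest", direction1 = ">=", direction2 = "<",
    min_quadrant_size = 10,
    data = data.frame(v1 = 1, v2 = 1, time = 1, event = 1),
    horizon_days = 365), class = "pv_landscape")
  # tie between (2,1) n=10 and (1,2) n=40: larger risk group wins
  got <- optimal_thresholds(skel)
  expect_equal(got$threshold1, 60)
  expect_equal(got$threshold2, 15)
  expect_equal(got$n_risk, 40L)
  expect_equal(got$p, 0.01)
  # unique minimum wins outright
  skel$p[1, 1] <- 1e-6
  got2 <- optimal_thresholds(skel)
  expect_equal(c(got2$threshold1, got2$threshold2), c(60, 14))
  skel$p[] <- NA_real_
  expect_error(optimal_thresholds(skel), "no evaluable")
})

test_that("planted thresholds are recovered within one grid step", {
  co <- generate_cohort(nep_rdw_only_config(2000, seed = 31))
  sub <- filter_stratum(apply_eligibility(co, rsf_eligibility_criteria()),
                        "without_te")
  ls <- pvalue_matrix(sub, "NEP", "RDW")
  opt <- optimal_thresholds(ls)
  near <- function(grid, got, target) {
    i_got <- which.min(abs(grid - got))
    i_tgt <- which.min(abs(grid - target))
    abs(i_got - i_tgt) <= 1L
  }
  expect_true(near(ls$grid1, opt$threshold1, 72.05))
  expect_true(near(ls$grid2, opt$threshold2, 14.3))
  # the best two-variable cell is at least as sharp as either median split
  out <- te_outcome(sub)
  idx <- match(out$patient_id, sub$patient_id)
  for (v in c("NEP", "RDW")) {
    x <- sub[[v]][idx]
    ok <- !is.na(x)
    p_med <- logrank_test(out$time[ok], out$event[ok],
                          x[ok] >= median(x[ok]))$p
    expect_lte(opt$p, p_med)
  }
})

test_that("decision trees encode the published-style boundary conventions", {
  tree_a <- build_decision_tree(var1 = "NEP", threshold1 = 72.05,
                                direction1 = ">=", var2 = "RDW",
                                threshold2 = 14.3, direction2 = "<")
  pts <- data.frame(NEP = c(75, 75, 70, 75), RDW = c(14.0, 14.3, 14.0, NA))
  got <- predict(tree_a, pts)
  expect_equal(got[1], "high risk")   # RDW 14.0, NEP 75
  expect_equal(got[2], "low risk")    # RDW exactly 14.3 fails "< 14.3"
  expect_equal(got[3], "low risk")    # NEP below the cut
  expect_true(is.na(got[4]))
  tree_b <- build_decision_tree(var1 = "RDW", threshold1 = 14.05,
                                direction1 = "<", var2 = "LYP",
                                threshold2 = 19.3, direction2 = "<")
  expect_equal(predict(tree_b, data.frame(RDW = 13.9, LYP = 18.0)),
               "high risk")
  # application is a pure function
  expect_identical(predict(tree_a, pts), predict(tree_a, pts))
})

test_that("a threshold pair from a landscape builds the same tree", {
  co <- generate_cohort(nep_rdw_only_config(800, seed = 37))
  ls <- pvalue_matrix(filter_stratum(co, "without_te"), "NEP", "RDW",
                      grid1 = c(70, 72), grid2 = c(14, 15))
  tree <- build_decision_tree(optimal_thresholds(ls))
  expect_s3_class(tree, "pv_dtree")
  expect_equal(tree$var1, "NEP")
  expect_equal(tree$direction2, "<")
})

test_that("fixed-threshold validation detects the planted signal and errors on empty leaves", {
  tree <- build_decision_tree(var1 = "NEP", threshold1 = 72.05,
                              direction1 = ">=", var2 = "RDW",
                              threshold2 = 14.3, direction2 = "<")
  vc <- generate_validation_cohort(n_patients = 300, seed = 41)
  val <- validate_fixed_thresholds(tree, vc)
  expect_s3_class(val$logrank, "pv_logrank")
  expect_gt(val$n_high, 0)
  expect_true(all(c("group", "surv") %in% names(val$km)))

  all_low <- vc
  all_low$NEP <- 60  # nobody clears the NEP cut
  expect_error(validate_fixed_thresholds(tree, all_low), "empty")
})

test_that("null landscapes are not Bonferroni-significant after permutation", {
  hits <- 0L
  for (s in 1:5) {
    co <- generate_cohort(flat_config(600, seed = 100 + s, hazard = 0.25,
                                      admin = c(1200, 1200)))
    sub <- filter_stratum(co, "without_te")
    ls <- pvalue_matrix(sub, "NEP", "RDW",
                        grid1 = quantile(sub$NEP, seq(0.1, 0.9, 0.1)),
                        grid2 = quantile(sub$RDW, seq(0.1, 0.9, 0.1)))
    n_cells <- sum(!is.na(ls$p))
    if (min(ls$p, na.rm = TRUE) * n_cells >= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("the permutation-adjusted minimum p flags selection optimism", {
  co <- generate_cohort(flat_config(400, seed = 51, hazard = 0.3,
                                    admin = c(1000, 1000)))
  ls <- pvalue_matrix(co, "NEP", "RDW",
                      grid1 = quantile(co$NEP, c(0.3, 0.5, 0.7), na.rm = TRUE),
                      grid2 = quantile(co$RDW, c(0.3, 0.5, 0.7), na.rm = TRUE))
  adj <- landscape_permutation_p(ls, n_perm = 60, seed = 8)
  expect_gte(adj$p_adjusted, adj$p_min)
  expect_lte(adj$p_adjusted, 1)
})
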